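#' Pairwise incremental cost-effectiveness comparison
#'
#' Computes incremental cost and QALYs (intervention minus comparator) and
#' classifies the comparison.  The ICER is defined only when the increments
#' do not indicate dominance: an intervention that is cheaper and more
#' effective is `intervention_dominant` (and symmetrically); equal QALYs
#' with unequal cost are classified by the cost sign without an ICER, and
#' identical results are `equal_effects`.
#'
#' @param intervention,comparator `strategy_result` objects
#'   (see [run_cohort()]), or any lists with `arm_name`, `total_cost`,
#'   `total_qaly`.
#' @return a `comparison_result` list: `intervention`, `comparator`,
#'   `delta_cost`, `delta_qaly`, `icer` (`NA` when undefined),
#'   `classification`.
#' @export
compare_strategies <- function(intervention, comparator) {
  stopifnot(is.finite(intervention$total_cost), is.finite(comparator$total_cost),
            is.finite(intervention$total_qaly), is.finite(comparator$total_qaly))
  dc <- intervention$total_cost - comparator$total_cost
  dq <- intervention$total_qaly - comparator$total_qaly
  if (dq == 0 && dc == 0) {
    cls <- "equal_effects"; icer <- NA_real_
  } else if (dq > 0 && dc < 0) {
    cls <- "intervention_dominant"; icer <- NA_real_
  } else if (dq < 0 && dc > 0) {
    cls <- "comparator_dominant"; icer <- NA_real_
  } else if (dq == 0) {
    cls <- if (dc < 0) "intervention_dominant" else "comparator_dominant"
    icer <- NA_real_
  } else {
    cls <- "icer_defined"; icer <- dc / dq
  }
  structure(
    list(intervention = intervention$arm_name,
         comparator = comparator$arm_name,
         delta_cost = dc, delta_qaly = dq,
         icer = icer, classification = cls),
    class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s vs %s: dC $%.2f, dQ %.4f, %s",
              x$intervention, x$comparator, x$delta_cost, x$delta_qaly,
              x$classification))
  if (!is.na(x$icer)) cat(sprintf(", ICER $%.2f/QALY", x$icer))
  cat("\n")
  invisible(x)
}

#' Net monetary benefit of a strategy
#'
#' `NMB = wtp * total_qaly - total_cost`; linear in the willingness-to-pay
#' threshold, so two strategies' NMB curves cross exactly at the ICER when
#' the QALY increment is positive.
#'
#' @param result a `strategy_result`.
#' @param wtp willingness-to-pay threshold (USD/QALY, non-negative).
#' @return USD.
#' @export
net_monetary_benefit <- function(result, wtp) {
  if (any(wtp < 0)) stop("`wtp` must be non-negative", call. = FALSE)
  wtp * result$total_qaly - result$total_cost
}

#' Willingness-to-pay verdict under the GDP-multiple rule
#'
#' An ICER strictly below 1x GDP per capita is `very_cost_effective`;
#' between 1x and strictly below 3x GDP, `cost_effective`; otherwise
#' `not_cost_effective`.  A dominant intervention is `dominant` at any GDP;
#' a dominated intervention is `not_cost_effective`; `equal_effects` without
#' an ICER is `not_classifiable`.
#'
#' @param comparison a `comparison_result` from [compare_strategies()].
#' @param gdp GDP per capita (USD, > 0).
#' @return a `wtp_decision` list: `icer`, `gdp_per_capita`, `verdict`.
#' @export
wtp_verdict <- function(comparison, gdp) {
  stopifnot(gdp > 0)
  verdict <-
    if (comparison$classification == "intervention_dominant") "dominant"
    else if (comparison$classification == "comparator_dominant") "not_cost_effective"
    else if (comparison$classification == "equal_effects") "not_classifiable"
    else if (comparison$icer < gdp) "very_cost_effective"
    else if (comparison$icer < 3 * gdp) "cost_effective"
    else "not_cost_effective"
  structure(list(icer = comparison$icer, gdp_per_capita = gdp,
                 verdict = verdict),
            class = "wtp_decision")
}

#' Tabulate base-case comparisons
#'
#' The machine twin of a base-case results table: one row per pairwise
#' comparison with increments, ICER, classification and WTP verdict.
#'
#' @param results named list of `strategy_result`.
#' @param comparisons list of `c(intervention, comparator)` name pairs;
#'   defaults to PP1M-vs-ER, PP3M-vs-ER and PP3M-vs-PP1M when those arms are
#'   present.
#' @param gdp GDP per capita used for the verdict.
#' @return data frame with columns `intervention`, `comparator`,
#'   `delta_cost`, `delta_qaly`, `icer`, `classification`, `verdict`.
#' @export
comparison_table <- function(results, comparisons = NULL, gdp = 12756.55) {
  if (is.null(comparisons)) {
    nm <- names(results)
    comparisons <- list()
    if (all(c("PP1M", "ER") %in% nm)) comparisons <- c(comparisons, list(c("PP1M", "ER")))
    if (all(c("PP3M", "ER") %in% nm)) comparisons <- c(comparisons, list(c("PP3M", "ER")))
    if (all(c("PP3M", "PP1M") %in% nm)) comparisons <- c(comparisons, list(c("PP3M", "PP1M")))
  }
  rows <- lapply(comparisons, function(pair) {
    cmp <- compare_strategies(results[[pair[1L]]], results[[pair[2L]]])
    data.frame(intervention = cmp$intervention, comparator = cmp$comparator,
               delta_cost = cmp$delta_cost, delta_qaly = cmp$delta_qaly,
               icer = cmp$icer, classification = cmp$classification,
               verdict = wtp_verdict(cmp, gdp)$verdict)
  })
  do.call(rbind, rows)
}
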