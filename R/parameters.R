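#' Constructors for model parameters
#'
#' A `model_param` bundles a point value with its sensitivity bounds and the
#' distribution family used in probabilistic sensitivity analysis.
#' Probabilities and utilities use `"beta"`, costs use `"gamma"`, and
#' `"fixed"` marks quantities that are never varied.
#'
#' @param value point estimate (per-cycle probability, per-cycle USD cost, or
#'   per-cycle QALY weight, depending on context).
#' @param low,high sensitivity bounds; default to `value` (a fixed parameter).
#' @param family one of `"beta"`, `"gamma"`, `"fixed"`.
#' @param basis for cost parameters, `"per_cycle"` or `"per_admission"`.
#' @param shared_id optional identifier tying several parameter slots to one
#'   underlying uncertain quantity (e.g. one drug price billed in several
#'   states); slots sharing an id move together in sensitivity analyses.
#' @return an object of class `ppcea_param`.
#' @export
model_param <- function(value, low = value, high = value,
                        family = c("fixed", "beta", "gamma"),
                        basis = NULL, shared_id = NULL) {
  family <- match.arg(family)
  stopifnot(is.numeric(value), length(value) == 1L, is.finite(value))
  x <- list(value = value, low = low, high = high, family = family)
  if (!is.null(basis)) {
    basis <- match.arg(basis, c("per_cycle", "per_admission"))
    x$basis <- basis
  }
  if (!is.null(shared_id)) x$shared_id <- shared_id
  structure(x, class = "ppcea_param")
}

#' @export
print.ppcea_param <- function(x, ...) {
  cat(sprintf("<ppcea_param> %g [%g, %g] (%s)\n",
              x$value, x$low, x$high, x$family))
  invisible(x)
}

#' Age-banded annual mortality table
#'
#' @param age_low,age_high integer band edges in years (inclusive); bands must
#'   be non-overlapping and in increasing order.
#' @param annual_probability annual probability of death in each band.
#' @return a data frame of class `mortality_table`.
#' @export
mortality_table <- function(age_low, age_high, annual_probability) {
  stopifnot(length(age_low) == length(age_high),
            length(age_low) == length(annual_probability))
  if (length(age_low) == 0L)
    stop("mortality table must have at least one band", call. = FALSE)
  if (is.unsorted(age_low, strictly = TRUE))
    stop("mortality bands must be in increasing age order", call. = FALSE)
  structure(
    data.frame(age_low = age_low, age_high = age_high,
               annual_probability = annual_probability),
    class = c("mortality_table", "data.frame"))
}

#' Per-strategy model parameters
#'
#' The per-cycle transition probabilities and drug costs of one treatment
#' arm.  All probabilities are per model cycle and, within the engine, are
#' interpreted as conditional on surviving the cycle.
#'
#' @param arm_name strategy identifier, e.g. `"PP1M"`.
#' @param p_disc_nonstable probability of remaining in the non-stable state
#'   (all-cause discontinuation while acute); complement moves to
#'   stable/adherent.
#' @param p_disc_stable probability of autonomous treatment discontinuation
#'   from the stable/adherent state (moves to stable/non-adherent).
#' @param p_relapse_stable relapse probability from stable/adherent.
#' @param p_relapse_nonadherent relapse probability from stable/non-adherent.
#' @param p_hosp_nonstable per-cycle hospitalization probability while
#'   non-stable (expectation-weights the admission cost).
#' @param drug_cost_cycle_stable,drug_cost_cycle_nonstable drug cost per
#'   cycle (USD) in stable/adherent and non-stable states.
#' @return an object of class `arm_parameters`.
#' @export
arm_parameters <- function(arm_name,
                           p_disc_nonstable, p_disc_stable,
                           p_relapse_stable, p_relapse_nonadherent,
                           p_hosp_nonstable,
                           drug_cost_cycle_stable, drug_cost_cycle_nonstable) {
  probs <- list(p_disc_nonstable = p_disc_nonstable,
                p_disc_stable = p_disc_stable,
                p_relapse_stable = p_relapse_stable,
                p_relapse_nonadherent = p_relapse_nonadherent,
                p_hosp_nonstable = p_hosp_nonstable)
  for (nm in names(probs))
    if (!inherits(probs[[nm]], "ppcea_param"))
      stop("`", nm, "` must be a ppcea_param", call. = FALSE)
  structure(
    c(list(arm_name = arm_name), probs,
      list(drug_cost_cycle_stable = drug_cost_cycle_stable,
           drug_cost_cycle_nonstable = drug_cost_cycle_nonstable)),
    class = "arm_parameters")
}

#' Global model configuration
#'
#' @param horizon_years simulation horizon in years.
#' @param cycle_months cycle length in months.
#' @param annual_discount_rate annual discount rate applied to both costs and
#'   QALYs; `discount_low`/`discount_high` give its one-way sensitivity range.
#' @param discount_low,discount_high sensitivity bounds for the discount rate.
#' @param start_age cohort age at model entry (years).
#' @param wtp_per_qaly willingness-to-pay threshold (USD/QALY).
#' @param utilities named list with `ppcea_param` entries `stable`,
#'   `non_stable`, `relapse` — per-cycle QALY weights.
#' @param shared_costs named list with `ppcea_param` entries
#'   `hospitalization` (per admission), `outpatient_stable`,
#'   `outpatient_nonstable` (per cycle, USD).
#' @param mortality a [mortality_table()].
#' @param relapse_hospitalization_policy `"never"` (default) or `"always"`:
#'   whether the one-cycle relapse state accrues a full admission cost on top
#'   of non-stable outpatient cost.
#' @return an object of class `model_config`.
#' @export
model_config <- function(horizon_years = 20,
                         cycle_months = 3,
                         annual_discount_rate = 0.05,
                         discount_low = 0,
                         discount_high = 0.08,
                         start_age = 38,
                         wtp_per_qaly = 12756.55,
                         utilities,
                         shared_costs,
                         mortality,
                         relapse_hospitalization_policy = c("never", "always")) {
  relapse_hospitalization_policy <- match.arg(relapse_hospitalization_policy)
  stopifnot(horizon_years >= 0, cycle_months > 0,
            annual_discount_rate >= 0, annual_discount_rate <= 1)
  n_cycles <- horizon_years * 12 / cycle_months
  if (abs(n_cycles - round(n_cycles)) > 1e-9)
    stop("horizon_years * 12 / cycle_months must be a whole number of cycles",
         call. = FALSE)
  structure(
    list(horizon_years = horizon_years,
         cycle_months = cycle_months,
         annual_discount_rate = annual_discount_rate,
         discount_low = discount_low,
         discount_high = discount_high,
         start_age = start_age,
         wtp_per_qaly = wtp_per_qaly,
         utilities = utilities,
         shared_costs = shared_costs,
         mortality = mortality,
         relapse_hospitalization_policy = relapse_hospitalization_policy),
    class = "model_config")
}

#' Number of cycles implied by a configuration
#' @param config a [model_config()].
#' @return integer cycle count.
#' @export
n_cycles <- function(config) {
  as.integer(round(config$horizon_years * 12 / config$cycle_months))
}

#' Convert an event rate over an observation window to a per-cycle probability
#'
#' Under a constant-hazard assumption, a proportion `rate` of subjects
#' experiencing an event over `window_months` implies hazard
#' `r = -log(1 - rate) / window_months`, and the probability over one model
#' cycle of length `cycle_months` is `1 - exp(-r * cycle_months)`.
#'
#' @param rate proportion experiencing the event, in `[0, 1]`.
#' @param window_months observation window (months, > 0).
#' @param cycle_months target cycle length (months, > 0).
#' @return per-cycle probability in `[0, 1]`.
#' @examples
#' rate_to_cycle_prob(0.1119, 12, 3)  # 0.0292 at 4 dp
#' @export
rate_to_cycle_prob <- function(rate, window_months, cycle_months) {
  if (any(rate < 0 | rate > 1))
    stop("`rate` must lie in [0, 1]", call. = FALSE)
  if (any(window_months <= 0) || any(cycle_months <= 0))
    stop("`window_months` and `cycle_months` must be positive", call. = FALSE)
  ifelse(rate == 1, 1,
         1 - exp(log1p(-rate) * cycle_months / window_months))
}

#' Invert a per-cycle probability back to a rate over a window
#'
#' Inverse of [rate_to_cycle_prob()] under the same constant-hazard model.
#'
#' @param prob per-cycle probability in `[0, 1)`.
#' @param cycle_months cycle length the probability refers to.
#' @param window_months target observation window.
#' @return event rate over `window_months`.
#' @export
cycle_prob_to_rate <- function(prob, cycle_months, window_months) {
  rate_to_cycle_prob(prob, cycle_months, window_months)
}

#' Convert an annual probability to a per-cycle probability
#'
#' @param q_annual annual probability in `[0, 1]`.
#' @param cycle_months cycle length in months.
#' @return `1 - (1 - q_annual)^(cycle_months / 12)`.
#' @export
annual_prob_to_cycle <- function(q_annual, cycle_months) {
  if (any(q_annual < 0 | q_annual > 1))
    stop("`q_annual` must lie in [0, 1]", call. = FALSE)
  if (any(cycle_months <= 0))
    stop("`cycle_months` must be positive", call. = FALSE)
  1 - (1 - q_annual)^(cycle_months / 12)
}

#' Per-cycle death probability at a given age
#'
#' Selects the mortality band containing `age` (clamping below the first and
#' above the last band) and converts its annual probability to the cycle
#' length.
#'
#' @param table a [mortality_table()].
#' @param age cohort age in years.
#' @param cycle_months cycle length in months.
#' @return per-cycle probability of death.
#' @export
mortality_for_age <- function(table, age, cycle_months) {
  if (!inherits(table, "mortality_table") || nrow(table) == 0L)
    stop("`table` must be a non-empty mortality_table", call. = FALSE)
  if (age < 0) stop("`age` must be non-negative", call. = FALSE)
  i <- findInterval(age, table$age_low)       # 0 below the first band
  i <- min(max(i, 1L), nrow(table))           # clamp to the table's edges
  annual_prob_to_cycle(table$annual_probability[i], cycle_months)
}

#' Drug cost over one cycle from a unit price and daily dose
#'
#' Used for scenario construction only; the reference fixture stores the
#' published per-cycle costs verbatim.
#'
#' @param price_per_mg USD per mg.
#' @param dose_mg_per_day mean daily dose (mg).
#' @param days_per_cycle days in one model cycle.
#' @return USD per cycle.
#' @export
drug_cost_per_cycle <- function(price_per_mg, dose_mg_per_day, days_per_cycle) {
  if (any(c(price_per_mg, dose_mg_per_day, days_per_cycle) < 0))
    stop("all inputs must be non-negative", call. = FALSE)
  price_per_mg * dose_mg_per_day * days_per_cycle
}

check_param_bounds <- function(p, id, probability = FALSE, out) {
  if (!(p$low <= p$value && p$value <= p$high))
    out <- c(out, sprintf("%s: bounds not ordered (low %g, value %g, high %g)",
                          id, p$low, p$value, p$high))
  if (p$low < 0)
    out <- c(out, sprintf("%s: negative lower bound %g", id, p$low))
  if (probability && p$high > 1)
    out <- c(out, sprintf("%s: upper bound %g exceeds 1", id, p$high))
  out
}

#' Validate a parameter set
#'
#' Checks every type invariant (probability and utility bounds in `[0, 1]`,
#' ordered sensitivity ranges, positive costs, well-formed mortality bands)
#' and each arm's conditional transition-mass feasibility
#' (`p_disc_stable + p_relapse_stable <= 1`).  Violations are returned, not
#' thrown.
#'
#' @param arms a list of [arm_parameters()].
#' @param config a [model_config()].
#' @return character vector of human-readable violations; empty when valid.
#' @export
validate_parameters <- function(arms, config) {
  out <- character()
  prob_fields <- c("p_disc_nonstable", "p_disc_stable", "p_relapse_stable",
                   "p_relapse_nonadherent", "p_hosp_nonstable")
  for (arm in arms) {
    for (f in prob_fields)
      out <- check_param_bounds(arm[[f]], paste0(arm$arm_name, ".", f),
                                probability = TRUE, out)
    for (f in c("drug_cost_cycle_stable", "drug_cost_cycle_nonstable"))
      out <- check_param_bounds(arm[[f]], paste0(arm$arm_name, ".", f), out = out)
    mass <- arm$p_disc_stable$value + arm$p_relapse_stable$value
    if (mass > 1)
      out <- c(out, sprintf(
        "%s: conditional transition mass from stable/adherent is %g > 1",
        arm$arm_name, mass))
  }
  for (u in names(config$utilities))
    out <- check_param_bounds(config$utilities[[u]], paste0("utility.", u),
                              probability = TRUE, out)
  for (s in names(config$shared_costs))
    out <- check_param_bounds(config$shared_costs[[s]], paste0("cost.", s),
                              out = out)
  mt <- config$mortality
  if (any(mt$annual_probability <= 0 | mt$annual_probability >= 1))
    out <- c(out, "mortality: annual probabilities must lie in (0, 1)")
  if (nrow(mt) > 1 && any(mt$age_low[-1] != mt$age_high[-nrow(mt)] + 1))
    out <- c(out, "mortality: bands are not contiguous in age")
  if (config$horizon_years < 0)
    out <- c(out, "config: horizon_years must be non-negative")
  out
}
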