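#' Reference parameter fixture
#'
#' The embedded base-case inputs of the published Chinese cost-utility
#' evaluation of paliperidone palmitate: per-cycle transition probabilities,
#' per-cycle drug costs (2022 USD), shared hospitalization/outpatient costs,
#' per-cycle EQ-5D-derived utility weights, the seven-band schizophrenia
#' mortality schedule, a 20-year horizon with 3-month cycles, 5%/yr
#' discounting and a willingness-to-pay threshold of $12,756.55/QALY.
#'
#' Utilities are stored per 3-month cycle (stable 0.23, non-stable and
#' relapse 0.15); the relapse state reuses the non-stable weight as both are
#' acute-symptom states.  The PP3M arm's non-stable drug cost equals PP1M's,
#' because acute patients receive only ER or PP1M.  The stable/non-adherent
#' state accrues no drug cost.
#'
#' @return a list with elements `arms` (named list of [arm_parameters()] for
#'   PP1M, PP3M and ER) and `config` (a [model_config()]).
#' @export
reference_parameters <- function() {
  beta_p <- function(v, lo, hi) model_param(v, lo, hi, "beta")
  gamma_c <- function(v, lo, hi, basis = "per_cycle", shared_id = NULL)
    model_param(v, lo, hi, "gamma", basis = basis, shared_id = shared_id)

  pp1m_cost <- gamma_c(958.87, 767.10, 1150.65, shared_id = "cost.drug_PP1M")
  er_cost <- gamma_c(759.09, 607.27, 910.91, shared_id = "cost.drug_ER")

  arms <- list(
    PP1M = arm_parameters(
      "PP1M",
      p_disc_nonstable      = beta_p(0.2140, 0.1926, 0.2354),
      p_disc_stable         = beta_p(0.0483, 0.0435, 0.0531),
      p_relapse_stable      = beta_p(0.0292, 0.0263, 0.0321),
      p_relapse_nonadherent = beta_p(0.4731, 0.4258, 0.5204),
      p_hosp_nonstable      = beta_p(0.0102, 0.0091, 0.0112),
      drug_cost_cycle_stable    = pp1m_cost,
      drug_cost_cycle_nonstable = pp1m_cost),
    PP3M = arm_parameters(
      "PP3M",
      p_disc_nonstable      = beta_p(0.2140, 0.1926, 0.2354),
      p_disc_stable         = beta_p(0.0434, 0.0391, 0.0477),
      p_relapse_stable      = beta_p(0.0240, 0.0216, 0.0264),
      p_relapse_nonadherent = beta_p(0.3465, 0.3119, 0.3812),
      p_hosp_nonstable      = beta_p(0.0076, 0.0071, 0.0083),
      drug_cost_cycle_stable    = gamma_c(813.64, 650.91, 976.36,
                                          shared_id = "cost.drug_PP3M"),
      # acute patients receive PP1M, so the non-stable cycle bills PP1M's cost
      drug_cost_cycle_nonstable = pp1m_cost),
    ER = arm_parameters(
      "ER",
      p_disc_nonstable      = beta_p(0.2831, 0.2548, 0.3114),
      p_disc_stable         = beta_p(0.1792, 0.1613, 0.1971),
      p_relapse_stable      = beta_p(0.2655, 0.2390, 0.2921),
      p_relapse_nonadherent = beta_p(0.9864, 0.8878, 1),
      p_hosp_nonstable      = beta_p(0.0503, 0.0453, 0.0554),
      drug_cost_cycle_stable    = er_cost,
      drug_cost_cycle_nonstable = er_cost))

  config <- model_config(
    horizon_years = 20,
    cycle_months = 3,
    annual_discount_rate = 0.05,
    discount_low = 0,
    discount_high = 0.08,
    start_age = 38,
    wtp_per_qaly = 12756.55,
    utilities = list(
      stable     = beta_p(0.23, 0.21, 0.25),
      non_stable = beta_p(0.15, 0.14, 0.17),
      relapse    = beta_p(0.15, 0.14, 0.17)),
    shared_costs = list(
      hospitalization      = gamma_c(1998.90, 1599.12, 2398.68,
                                     basis = "per_admission"),
      outpatient_stable    = gamma_c(127.52, 102.02, 153.03),
      outpatient_nonstable = gamma_c(183.30, 164.97, 219.96)),
    mortality = mortality_table(
      age_low  = c(35, 40, 45, 50, 55, 60, 65),
      age_high = c(39, 44, 49, 54, 59, 64, 78),
      annual_probability = c(0.006267, 0.004904, 0.007708, 0.007606,
                             0.011745, 0.035610, 0.016676)),
    relapse_hospitalization_policy = "never")

  list(arms = arms, config = config)
}

#' Flatten a parameter set to one row per parameter
#'
#' The machine-readable twin of the published input table: one row per
#' parameter with its block, arm, value, sensitivity range, distribution
#' family and basis.
#'
#' @param params a list with `arms` and `config`, as returned by
#'   [reference_parameters()].
#' @return a data frame with columns `block`, `arm`, `parameter`, `value`,
#'   `low`, `high`, `distribution`, `basis`.
#' @export
parameter_table <- function(params = reference_parameters()) {
  rows <- list()
  add <- function(block, arm, parameter, p) {
    rows[[length(rows) + 1L]] <<- data.frame(
      block = block, arm = arm, parameter = parameter,
      value = p$value, low = p$low, high = p$high,
      distribution = p$family,
      basis = if (is.null(p$basis)) NA_character_ else p$basis)
  }
  prob_fields <- c("p_disc_nonstable", "p_disc_stable", "p_relapse_stable",
                   "p_relapse_nonadherent", "p_hosp_nonstable")
  for (arm in params$arms) {
    for (f in prob_fields) add("probability", arm$arm_name, f, arm[[f]])
    add("cost", arm$arm_name, "drug_cost_cycle_stable",
        arm$drug_cost_cycle_stable)
    add("cost", arm$arm_name, "drug_cost_cycle_nonstable",
        arm$drug_cost_cycle_nonstable)
  }
  for (u in names(params$config$utilities))
    add("utility", NA_character_, u, params$config$utilities[[u]])
  for (s in names(params$config$shared_costs))
    add("cost", NA_character_, s, params$config$shared_costs[[s]])
  mt <- params$config$mortality
  for (i in seq_len(nrow(mt)))
    rows[[length(rows) + 1L]] <- data.frame(
      block = "mortality", arm = NA_character_,
      parameter = sprintf("age_%d_%d", mt$age_low[i], mt$age_high[i]),
      value = mt$annual_probability[i], low = NA_real_, high = NA_real_,
      distribution = "fixed", basis = NA_character_)
  do.call(rbind, rows)
}
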