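# Shared fixtures built in code.

ref <- reference_parameters()

# Single-living-state toy: the whole cohort stays non-stable conditional on
# survival, per-cycle survival 0.9 (annual mortality 1 - 0.9^4), cost 100
# USD per cycle, utility weight 1, no discounting.
toy_params <- function(n_cycles = 2) {
  arm <- arm_parameters(
    "TOY",
    p_disc_nonstable = model_param(1),        # stay non-stable if alive
    p_disc_stable = model_param(0),
    p_relapse_stable = model_param(0),
    p_relapse_nonadherent = model_param(0),
    p_hosp_nonstable = model_param(0),
    drug_cost_cycle_stable = model_param(0),
    drug_cost_cycle_nonstable = model_param(100))
  config <- model_config(
    horizon_years = n_cycles * 3 / 12,
    cycle_months = 3,
    annual_discount_rate = 0,
    start_age = 38,
    utilities = list(stable = model_param(1),
                     non_stable = model_param(1),
                     relapse = model_param(1)),
    shared_costs = list(hospitalization = model_param(0, basis = "per_admission"),
                        outpatient_stable = model_param(0),
                        outpatient_nonstable = model_param(0)),
    mortality = mortality_table(0, 200, 1 - 0.9^4))
  list(arms = list(TOY = arm), config = config)
}

# A corrected-trace matrix pinning the whole cohort in one state.
pinned_corrected <- function(state, n_cycles) {
  m <- matrix(0, n_cycles, 5, dimnames = list(NULL, state_names()))
  m[, state] <- 1
  m
}

# Copy of a parameter set with every distribution family forced to "fixed".
all_fixed <- function(params) {
  for (a in names(params$arms))
    for (f in c(ppcea:::arm_prob_fields(),
                "drug_cost_cycle_stable", "drug_cost_cycle_nonstable"))
      params$arms[[a]][[f]]$family <- "fixed"
  for (u in names(params$config$utilities))
    params$config$utilities[[u]]$family <- "fixed"
  for (s in names(params$config$shared_costs))
    params$config$shared_costs[[s]]$family <- "fixed"
  params
}
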