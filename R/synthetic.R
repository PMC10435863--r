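#' Specification for a random synthetic parameter set
#'
#' The generator emulates the statistical shape of a complete decision-model
#' input table: per-cycle probabilities, positive per-cycle costs, per-cycle
#' utility weights and an age-banded mortality schedule.  Sampling is
#' uniform within the stated ranges — the aim is coverage of the valid
#' parameter space, not mimicry of any PSA distribution.
#'
#' @param seed RNG seed.
#' @param n_arms number of treatment arms.
#' @param probability_range range for per-cycle transition probabilities.
#' @param cost_range range for per-cycle / per-admission costs (USD).
#' @param utility_range range for per-cycle utility weights.
#' @param horizon_years simulation horizon.
#' @param mortality_level scale of the annual mortality probabilities.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1, n_arms = 3,
                           probability_range = c(0.005, 0.4),
                           cost_range = c(50, 2500),
                           utility_range = c(0.1, 0.25),
                           horizon_years = 20,
                           mortality_level = 0.01) {
  stopifnot(probability_range[1] >= 0, probability_range[2] <= 1,
            probability_range[1] < probability_range[2],
            cost_range[1] >= 0, cost_range[1] < cost_range[2],
            utility_range[1] >= 0, utility_range[2] <= 1,
            utility_range[1] < utility_range[2],
            horizon_years > 0, mortality_level > 0, mortality_level < 1)
  structure(list(seed = seed, n_arms = n_arms,
                 probability_range = probability_range,
                 cost_range = cost_range, utility_range = utility_range,
                 horizon_years = horizon_years,
                 mortality_level = mortality_level),
            class = "synthetic_spec")
}

runif1 <- function(range) stats::runif(1, range[1], range[2])

synth_prob <- function(range) {
  v <- runif1(range)
  model_param(v, max(0, v * 0.9), min(1, v * 1.1), "beta")
}

synth_cost <- function(range, basis = "per_cycle", shared_id = NULL) {
  v <- runif1(range)
  model_param(v, v * 0.8, v * 1.2, "gamma", basis = basis,
              shared_id = shared_id)
}

#' Draw a random, always-valid parameter set
#'
#' Every arm and configuration field is drawn uniformly within the spec's
#' ranges; draws violating conditional-mass feasibility
#' (`p_disc_stable + p_relapse_stable > 1`) are rejected and redrawn, up to
#' 1,000 attempts.  The output always passes [validate_parameters()] and is
#' reproducible from the seed.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `arms` and `config`.
#' @export
random_parameter_set <- function(spec = synthetic_spec()) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  pr <- spec$probability_range
  arms <- list()
  for (i in seq_len(spec$n_arms)) {
    nm <- paste0("ARM", i)
    for (attempt in seq_len(1000L)) {
      pds <- synth_prob(pr); prs <- synth_prob(pr)
      if (pds$value + prs$value <= 1 && pds$high + prs$high <= 1) break
      if (attempt == 1000L)
        stop("could not draw a feasible arm within 1,000 attempts",
             call. = FALSE)
    }
    drug <- synth_cost(spec$cost_range)
    arms[[nm]] <- arm_parameters(
      nm,
      p_disc_nonstable = synth_prob(pr),
      p_disc_stable = pds,
      p_relapse_stable = prs,
      p_relapse_nonadherent = synth_prob(pr),
      p_hosp_nonstable = synth_prob(pr),
      drug_cost_cycle_stable = drug,
      drug_cost_cycle_nonstable = drug)
  }
  ur <- spec$utility_range
  u_stable <- runif1(c(mean(ur), ur[2]))
  u_acute <- runif1(c(ur[1], u_stable))      # acute states no better than stable
  mk_u <- function(v) model_param(v, max(0, v * 0.9), min(1, v * 1.1), "beta")
  q5 <- spec$mortality_level
  bands <- mortality_table(
    age_low = c(35, 45, 55, 65),
    age_high = c(44, 54, 64, 100),
    annual_probability = pmin(0.99, q5 * c(0.5, 1, 2, 4)))
  config <- model_config(
    horizon_years = spec$horizon_years,
    cycle_months = 3,
    annual_discount_rate = stats::runif(1, 0, 0.08),
    start_age = 38,
    wtp_per_qaly = 12756.55,
    utilities = list(stable = mk_u(u_stable),
                     non_stable = mk_u(u_acute),
                     relapse = mk_u(u_acute)),
    shared_costs = list(
      hospitalization = synth_cost(spec$cost_range, basis = "per_admission"),
      outpatient_stable = synth_cost(spec$cost_range),
      outpatient_nonstable = synth_cost(spec$cost_range)),
    mortality = bands,
    relapse_hospitalization_policy = "never")
  out <- list(arms = arms, config = config)
  v <- validate_parameters(out$arms, out$config)
  if (length(v)) stop("synthetic generator produced an invalid set: ",
                      paste(v, collapse = "; "), call. = FALSE)
  out
}

#' Analytically tractable degenerate fixtures
#'
#' Named single-arm (plus reference-shaped) edge cases with closed-form
#' behaviour, for exact engine tests: `no_relapse` (both relapse
#' probabilities zero), `no_mortality` (mortality numerically zero),
#' `immediate_death` (annual mortality ~1), `zero_discount`, and
#' `single_cycle` (one-cycle horizon).
#'
#' @param kind fixture identifier.
#' @return list with `arms` and `config`.
#' @export
degenerate_fixture <- function(kind = c("no_relapse", "no_mortality",
                                        "immediate_death", "zero_discount",
                                        "single_cycle")) {
  kind <- match.arg(kind)
  params <- reference_parameters()
  tiny <- 1e-12
  if (kind == "no_relapse") {
    for (a in names(params$arms)) {
      params$arms[[a]]$p_relapse_stable <- model_param(0)
      params$arms[[a]]$p_relapse_nonadherent <- model_param(0)
    }
  } else if (kind == "no_mortality") {
    params$config$mortality$annual_probability[] <- tiny
  } else if (kind == "immediate_death") {
    params$config$mortality$annual_probability[] <- 1 - tiny
  } else if (kind == "zero_discount") {
    params$config$annual_discount_rate <- 0
  } else if (kind == "single_cycle") {
    params$config$horizon_years <- params$config$cycle_months / 12
  }
  params
}

#' Randomly perturbed copy of the reference fixture
#'
#' Multiplies every uncertain parameter of the reference fixture by an
#' independent uniform factor in `[1 - epsilon, 1 + epsilon]`, re-clamping
#' probabilities and utilities to `[0, 1]` and keeping bounds ordered.  Used
#' for robustness checks of qualitative conclusions.
#'
#' @param epsilon relative perturbation magnitude in `[0, 0.5]`.
#' @param seed RNG seed.
#' @return list with `arms` and `config`, always passing
#'   [validate_parameters()].
#' @export
perturbed_reference <- function(epsilon, seed = 1) {
  stopifnot(epsilon >= 0, epsilon <= 0.5)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  params <- reference_parameters()
  up <- uncertain_parameters(params)
  up <- up[up$family %in% c("beta", "gamma"), , drop = FALSE]
  for (i in seq_len(nrow(up))) {
    v <- up$mean[i] * stats::runif(1, 1 - epsilon, 1 + epsilon)
    if (up$family[i] == "beta") v <- min(max(v, 0), 1)
    params <- set_parameter(params, up$id[i], v)
  }
  # clamp bounds around the moved point values so the set still validates
  fix <- function(p, probability) {
    p$low <- min(p$low, p$value)
    p$high <- max(p$high, p$value)
    if (probability) p$high <- min(p$high, 1)
    p
  }
  for (a in names(params$arms)) {
    for (f in arm_prob_fields())
      params$arms[[a]][[f]] <- fix(params$arms[[a]][[f]], TRUE)
    for (f in c("drug_cost_cycle_stable", "drug_cost_cycle_nonstable"))
      params$arms[[a]][[f]] <- fix(params$arms[[a]][[f]], FALSE)
    mass <- params$arms[[a]]$p_disc_stable$value +
      params$arms[[a]]$p_relapse_stable$value
    if (mass > 1) {   # epsilon <= 0.5 keeps reference masses < 1, but be safe
      params$arms[[a]]$p_relapse_stable$value <-
        params$arms[[a]]$p_relapse_stable$value / mass
    }
  }
  for (u in names(params$config$utilities))
    params$config$utilities[[u]] <- fix(params$config$utilities[[u]], TRUE)
  for (s in names(params$config$shared_costs))
    params$config$shared_costs[[s]] <- fix(params$config$shared_costs[[s]], FALSE)
  params
}
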