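#' Health-state identifiers
#'
#' The five mutually exclusive states of the cohort model, in the fixed
#' order used by every matrix and trace: non-stable (acute), stable and
#' adherent to treatment, stable but self-discontinued, relapse (a one-cycle
#' tunnel back to non-stable), and death (absorbing).
#'
#' @return character vector of length five.
#' @export
state_names <- function() {
  c("non_stable", "stable_adherent", "stable_nonadherent", "relapse", "death")
}

#' Build the one-cycle transition matrix for an arm at a given cohort age
#'
#' Mortality is a competing risk applied first: the per-cycle death
#' probability `q` for the cohort's current age applies from every living
#' state, and the printed transition probabilities act conditionally on
#' surviving the cycle, scaled by `1 - q`.  Conditional moves: non-stable
#' patients remain non-stable with the discontinuation probability and
#' otherwise stabilize; stable/adherent patients discontinue, relapse, or
#' stay; stable/non-adherent patients relapse or stay (no return to
#' adherence); relapse is a one-cycle tunnel whose survivors re-enter the
#' non-stable state.
#'
#' @param arm an [arm_parameters()].
#' @param config a [model_config()].
#' @param age cohort age in years at the start of the cycle.
#' @return a 5x5 row-stochastic matrix with `state_names()` dimnames.
#' @export
build_transition_matrix <- function(arm, config, age) {
  q <- mortality_for_age(config$mortality, age, config$cycle_months)
  pdn <- arm$p_disc_nonstable$value
  pds <- arm$p_disc_stable$value
  prs <- arm$p_relapse_stable$value
  prn <- arm$p_relapse_nonadherent$value
  if (pds + prs > 1)
    stop(sprintf("%s: p_disc_stable + p_relapse_stable = %g exceeds 1",
                 arm$arm_name, pds + prs), call. = FALSE)
  s <- state_names()
  M <- matrix(0, 5, 5, dimnames = list(s, s))
  M[1, ] <- c(pdn, 1 - pdn, 0, 0, 0) * (1 - q)
  M[2, ] <- c(0, 1 - pds - prs, pds, prs, 0) * (1 - q)
  M[3, ] <- c(0, 0, 1 - prn, prn, 0) * (1 - q)
  M[4, ] <- c(1 - q, 0, 0, 0, 0)
  M[, 5] <- c(q, q, q, q, 1)
  M
}

#' Half-cycle correction of a membership trace
#'
#' Averages memberships at consecutive cycle boundaries so that accruals
#' approximate mid-cycle exposure: `corrected[k, ] =
#' (memberships[k, ] + memberships[k + 1, ]) / 2`.
#'
#' @param memberships numeric matrix with `N + 1` rows (cycle boundaries
#'   `0..N`) and one column per state.
#' @return matrix with `N` rows of corrected memberships.
#' @export
half_cycle_correct <- function(memberships) {
  if (nrow(memberships) < 2L)
    stop("need at least two time points for half-cycle correction",
         call. = FALSE)
  (memberships[-nrow(memberships), , drop = FALSE] +
     memberships[-1L, , drop = FALSE]) / 2
}

#' Mid-cycle discount factor
#'
#' Uses the mid-cycle exponent convention, consistent with half-cycle
#' correction: cycle `k` is discounted by
#' `(1 + r)^(-(k - 0.5) * cycle_months / 12)`.
#'
#' @param cycle_index cycle number, starting at 1.
#' @param config a [model_config()] (fields `annual_discount_rate`,
#'   `cycle_months`).
#' @return discount factor(s) in `(0, 1]`.
#' @export
discount_factor <- function(cycle_index, config) {
  (1 + config$annual_discount_rate) ^
    (-(cycle_index - 0.5) * config$cycle_months / 12)
}

#' Per-state per-cycle costs for one arm (USD)
#'
#' Non-stable: drug + non-stable outpatient + expected hospitalization
#' (probability-weighted admission cost).  Stable/adherent: drug + stable
#' outpatient.  Stable/non-adherent: stable outpatient only (treatment
#' discontinued).  Relapse: non-stable outpatient, plus a full admission when
#' `relapse_hospitalization_policy = "always"`.  Death: 0.
#'
#' @param arm an [arm_parameters()].
#' @param config a [model_config()].
#' @return named numeric vector over `state_names()`.
#' @export
state_costs <- function(arm, config) {
  sc <- config$shared_costs
  relapse_cost <- sc$outpatient_nonstable$value +
    if (config$relapse_hospitalization_policy == "always")
      sc$hospitalization$value else 0
  c(non_stable = arm$drug_cost_cycle_nonstable$value +
      sc$outpatient_nonstable$value +
      arm$p_hosp_nonstable$value * sc$hospitalization$value,
    stable_adherent = arm$drug_cost_cycle_stable$value +
      sc$outpatient_stable$value,
    stable_nonadherent = sc$outpatient_stable$value,
    relapse = relapse_cost,
    death = 0)
}

#' Per-state per-cycle QALY weights
#' @param config a [model_config()].
#' @return named numeric vector over `state_names()`.
#' @export
state_utilities <- function(config) {
  u <- config$utilities
  c(non_stable = u$non_stable$value,
    stable_adherent = u$stable$value,
    stable_nonadherent = u$stable$value,
    relapse = u$relapse$value,
    death = 0)
}

#' Accrue discounted costs and QALYs over a corrected trace
#'
#' Per cycle `k`, the cycle cost is the corrected-membership-weighted sum of
#' state costs times the mid-cycle discount factor, and likewise for QALYs.
#'
#' @param corrected matrix of half-cycle-corrected memberships
#'   (rows = cycles `1..N`).
#' @param arm an [arm_parameters()].
#' @param config a [model_config()].
#' @return a `strategy_result` list: `arm_name`, `total_cost`, `total_qaly`,
#'   `per_cycle_costs`, `per_cycle_qalys`.
#' @export
accumulate <- function(corrected, arm, config) {
  N <- nrow(corrected)
  df <- if (N > 0) discount_factor(seq_len(N), config) else numeric()
  cc <- as.vector(corrected %*% state_costs(arm, config)) * df
  cq <- as.vector(corrected %*% state_utilities(config)) * df
  structure(
    list(arm_name = arm$arm_name,
         total_cost = sum(cc), total_qaly = sum(cq),
         per_cycle_costs = cc, per_cycle_qalys = cq),
    class = "strategy_result")
}

#' @export
print.strategy_result <- function(x, ...) {
  cat(sprintf("<strategy_result> %s: cost $%.2f, QALYs %.4f (%d cycles)\n",
              x$arm_name, x$total_cost, x$total_qaly,
              length(x$per_cycle_costs)))
  invisible(x)
}

#' Run the cohort model for one arm
#'
#' The whole cohort starts in the non-stable state.  Memberships advance by
#' the age-appropriate transition matrix (the matrix is rebuilt as the
#' cohort ages across mortality bands; all other parameters are constant
#' over the horizon).  The trace is half-cycle corrected, then discounted
#' costs and QALYs are accrued with [accumulate()].
#'
#' @param arm an [arm_parameters()].
#' @param config a [model_config()].
#' @param n_cycles optional override of the cycle count (used for truncated
#'   horizons); defaults to `horizon_years * 12 / cycle_months`.
#' @return list with `trace` (a data frame: cycle, age, memberships,
#'   corrected memberships, discount factor, cycle cost, cycle QALY) and
#'   `result` (a `strategy_result`).
#' @export
run_cohort <- function(arm, config, n_cycles = NULL) {
  N <- if (is.null(n_cycles)) ppcea::n_cycles(config) else as.integer(n_cycles)
  s <- state_names()
  m <- matrix(0, N + 1L, 5L, dimnames = list(NULL, s))
  m[1L, 1L] <- 1
  cycle_years <- config$cycle_months / 12
  for (k in seq_len(N)) {
    age <- config$start_age + (k - 1L) * cycle_years
    M <- build_transition_matrix(arm, config, age)
    m[k + 1L, ] <- m[k, ] %*% M
  }
  corrected <- if (N > 0) half_cycle_correct(m) else m[0, , drop = FALSE]
  result <- accumulate(corrected, arm, config)
  trace <- data.frame(
    cycle = 0:N,
    age = config$start_age + (0:N) * cycle_years)
  trace[s] <- m
  trace[paste0("corrected_", s)] <-
    rbind(NA_real_, if (N > 0) corrected else NULL)[seq_len(N + 1L), ]
  trace$discount <- c(NA_real_,
                      if (N > 0) discount_factor(seq_len(N), config))
  trace$cycle_cost <- c(NA_real_, result$per_cycle_costs)
  trace$cycle_qaly <- c(NA_real_, result$per_cycle_qalys)
  list(trace = trace, result = result)
}

#' Run all arms of a parameter set
#'
#' @param params list with `arms` and `config`.
#' @param n_cycles optional truncated horizon.
#' @return named list of `strategy_result`, one per arm.
#' @export
run_all_arms <- function(params, n_cycles = NULL) {
  lapply(params$arms, function(a) run_cohort(a, params$config, n_cycles)$result)
}

#' Individual-level microsimulation oracle
#'
#' Simulates `n_individuals` independent trajectories through exactly the
#' same per-cycle transition matrices as [run_cohort()], accruing half-cycle
#' corrected, discounted costs and QALYs per individual.  Serves as an
#' independent stochastic check on the cohort engine: by the law of large
#' numbers the mean cost/QALY converge to the cohort totals.
#'
#' @param arm an [arm_parameters()].
#' @param config a [model_config()].
#' @param n_individuals number of simulated patients.
#' @param seed RNG seed; runs are bit-reproducible.
#' @return list with `arm_name`, `total_cost`, `total_qaly` (means),
#'   `se_cost`, `se_qaly` (Monte Carlo standard errors), `n`.
#' @export
microsim_oracle <- function(arm, config, n_individuals, seed) {
  stopifnot(n_individuals >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  N <- n_cycles(config)
  cost_vec <- state_costs(arm, config)
  util_vec <- state_utilities(config)
  cycle_years <- config$cycle_months / 12
  n <- as.integer(n_individuals)
  state <- rep(1L, n)
  tot_c <- numeric(n)
  tot_q <- numeric(n)
  for (k in seq_len(N)) {
    age <- config$start_age + (k - 1L) * cycle_years
    M <- build_transition_matrix(arm, config, age)
    cum <- t(apply(M, 1L, cumsum))
    u <- stats::runif(n)
    new_state <- integer(n)
    for (s in unique(state)) {
      idx <- state == s
      new_state[idx] <- findInterval(u[idx], cum[s, ], left.open = TRUE) + 1L
    }
    df <- discount_factor(k, config)
    half_c <- (cost_vec[state] + cost_vec[new_state]) / 2
    half_q <- (util_vec[state] + util_vec[new_state]) / 2
    tot_c <- tot_c + half_c * df
    tot_q <- tot_q + half_q * df
    state <- new_state
  }
  list(arm_name = arm$arm_name,
       total_cost = mean(tot_c), total_qaly = mean(tot_q),
       se_cost = stats::sd(tot_c) / sqrt(n),
       se_qaly = stats::sd(tot_q) / sqrt(n),
       n = n)
}
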