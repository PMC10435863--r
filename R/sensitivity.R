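#' Method-of-moments Beta fit from a mean and a 95% range
#'
#' Ranges are read as 95% intervals, `sd = (high - low) / 3.92`.  With
#' `nu = mean (1 - mean) / sd^2 - 1`, the fitted shapes are
#' `alpha = mean nu` and `beta = (1 - mean) nu`; the fit reproduces the
#' requested mean and sd exactly.
#'
#' @param mean mean in `(0, 1)`.
#' @param low,high interval bounds, `low < high`.
#' @return list of class `parameter_distribution`: `family = "beta"`,
#'   `mean`, `low`, `high`, `sd`, `alpha`, `beta`.
#' @export
fit_beta <- function(mean, low, high) {
  if (mean <= 0 || mean >= 1) stop("`mean` must lie in (0, 1)", call. = FALSE)
  if (low >= high) stop("`low` must be below `high`", call. = FALSE)
  sd <- (high - low) / 3.92
  if (sd^2 >= mean * (1 - mean))
    stop(sprintf("infeasible moments: variance %g >= mean(1-mean) %g",
                 sd^2, mean * (1 - mean)), call. = FALSE)
  nu <- mean * (1 - mean) / sd^2 - 1
  structure(list(family = "beta", mean = mean, low = low, high = high,
                 sd = sd, alpha = mean * nu, beta = (1 - mean) * nu),
            class = "parameter_distribution")
}

#' Method-of-moments Gamma fit from a mean and a 95% range
#'
#' `sd = (high - low) / 3.92`; `shape = mean^2 / sd^2`,
#' `scale = sd^2 / mean`, so `shape * scale = mean` exactly.
#'
#' @param mean mean (> 0, USD).
#' @param low,high interval bounds, `low < high`.
#' @return list of class `parameter_distribution`: `family = "gamma"`,
#'   `mean`, `low`, `high`, `sd`, `shape`, `scale`.
#' @export
fit_gamma <- function(mean, low, high) {
  if (mean <= 0) stop("`mean` must be positive", call. = FALSE)
  if (low >= high) stop("`low` must be below `high`", call. = FALSE)
  sd <- (high - low) / 3.92
  structure(list(family = "gamma", mean = mean, low = low, high = high,
                 sd = sd, shape = mean^2 / sd^2, scale = sd^2 / mean),
            class = "parameter_distribution")
}

#' Fit the PSA distribution declared by a parameter
#'
#' @param p a [model_param()].
#' @return a `parameter_distribution`; family `"fixed"` when the parameter
#'   declares no uncertainty (or a degenerate range).
#' @export
fit_distribution <- function(p) {
  if (p$family == "fixed" || p$low >= p$high)
    return(structure(list(family = "fixed", mean = p$value,
                          low = p$low, high = p$high),
                     class = "parameter_distribution"))
  switch(p$family,
         beta = fit_beta(p$value, p$low, p$high),
         gamma = fit_gamma(p$value, p$low, p$high))
}

draw_distribution <- function(d, n = 1L) {
  switch(d$family,
         fixed = rep(d$mean, n),
         beta = stats::rbeta(n, d$alpha, d$beta),
         gamma = stats::rgamma(n, shape = d$shape, scale = d$scale))
}

arm_prob_fields <- function() {
  c("p_disc_nonstable", "p_disc_stable", "p_relapse_stable",
    "p_relapse_nonadherent", "p_hosp_nonstable")
}

#' Registry of uncertain parameters
#'
#' Enumerates every distinct uncertain quantity of a parameter set with a
#' stable identifier: per-arm transition probabilities
#' (`"<arm>.<field>"`), one drug-price parameter per arm
#' (`"cost.drug_<arm>"`; a drug's price drives every cycle cost it appears
#' in, including the PP1M price billed in the PP3M arm's non-stable state),
#' shared costs (`"cost.<name>"`), utilities (`"utility.stable"`,
#' `"utility.non_stable"`, the latter also driving the relapse weight), and
#' the annual discount rate (`"config.annual_discount_rate"`, one-way
#' analysis only, never drawn in PSA).
#'
#' @param params list with `arms` and `config`.
#' @return data frame with columns `id`, `family`, `mean`, `low`, `high`.
#' @export
uncertain_parameters <- function(params) {
  rows <- list()
  add <- function(id, p, family = p$family) {
    rows[[length(rows) + 1L]] <<- data.frame(
      id = id, family = family, mean = p$value, low = p$low, high = p$high)
  }
  for (arm in params$arms)
    for (f in arm_prob_fields())
      add(paste0(arm$arm_name, ".", f), arm[[f]])
  seen <- character()
  for (arm in params$arms) {
    for (slot in c("drug_cost_cycle_stable", "drug_cost_cycle_nonstable")) {
      p <- arm[[slot]]
      id <- if (!is.null(p$shared_id)) p$shared_id
            else paste0("cost.drug_", arm$arm_name)
      if (!id %in% seen) { add(id, p); seen <- c(seen, id) }
    }
  }
  for (s in names(params$config$shared_costs))
    add(paste0("cost.", s), params$config$shared_costs[[s]])
  for (u in setdiff(names(params$config$utilities), "relapse"))
    add(paste0("utility.", u), params$config$utilities[[u]])
  rows[[length(rows) + 1L]] <- data.frame(
    id = "config.annual_discount_rate", family = "range_only",
    mean = params$config$annual_discount_rate,
    low = params$config$discount_low, high = params$config$discount_high)
  df <- do.call(rbind, rows)
  df[df$low < df$high, , drop = FALSE]
}

#' Set one uncertain parameter by id
#'
#' Applies the linkage documented in [uncertain_parameters()]: drug prices
#' propagate to every slot billing that drug; the non-stable utility also
#' sets the relapse weight.
#'
#' @param params list with `arms` and `config`.
#' @param id parameter identifier from [uncertain_parameters()].
#' @param value new point value.
#' @return modified `params`.
#' @export
set_parameter <- function(params, id, value) {
  if (id == "config.annual_discount_rate") {
    params$config$annual_discount_rate <- value
    return(params)
  }
  parts <- strsplit(id, ".", fixed = TRUE)[[1L]]
  head <- parts[1L]; field <- paste(parts[-1L], collapse = ".")
  if (head == "cost" && startsWith(field, "drug_")) {
    arm_nm <- sub("^drug_", "", field)
    hit <- FALSE
    for (a in names(params$arms)) {
      for (slot in c("drug_cost_cycle_stable", "drug_cost_cycle_nonstable"))
        if (identical(params$arms[[a]][[slot]]$shared_id, id)) {
          params$arms[[a]][[slot]]$value <- value
          hit <- TRUE
        }
    }
    if (!hit) {
      # arms without shared price ids bill their own drug in both states
      params$arms[[arm_nm]]$drug_cost_cycle_stable$value <- value
      params$arms[[arm_nm]]$drug_cost_cycle_nonstable$value <- value
    }
    return(params)
  }
  if (head == "cost") {
    params$config$shared_costs[[field]]$value <- value
    return(params)
  }
  if (head == "utility") {
    params$config$utilities[[field]]$value <- value
    if (field == "non_stable") params$config$utilities$relapse$value <- value
    return(params)
  }
  if (!head %in% names(params$arms) || !field %in% arm_prob_fields())
    stop("unknown parameter id: ", id, call. = FALSE)
  params$arms[[head]][[field]]$value <- value
  params
}

icer_for <- function(params, intervention, comparator, n_cycles = NULL) {
  ri <- run_cohort(params$arms[[intervention]], params$config, n_cycles)$result
  rc <- run_cohort(params$arms[[comparator]], params$config, n_cycles)$result
  compare_strategies(ri, rc)
}

#' One-way (tornado) sensitivity analysis
#'
#' Sets each uncertain parameter to its low then high bound (all others at
#' base), reruns both arms of the comparison, and records the cost-per-QALY
#' ratio at each bound.  The ratio is reported raw (incremental cost over
#' incremental QALYs): a bar crossing zero means the intervention becomes
#' dominant at that bound.  A bound with zero incremental QALYs, or one
#' that makes the model unbuildable, is flagged rather than silently
#' dropped.  Entries are sorted by width, widest first, ties broken by
#' `parameter_id`.
#'
#' @param params list with `arms` and `config`.
#' @param intervention,comparator arm names.
#' @return data frame of class `tornado_result`: `parameter_id`, `low`,
#'   `high` (input bounds), `icer_low`, `icer_high`, `width`, `flagged`;
#'   the base-case ICER is kept in attribute `base_icer`.
#' @export
tornado <- function(params, intervention, comparator = "ER") {
  up <- uncertain_parameters(params)
  base_icer <- icer_for(params, intervention, comparator)$icer
  rows <- lapply(seq_len(nrow(up)), function(i) {
    icers <- vapply(c(up$low[i], up$high[i]), function(v) {
      cmp <- tryCatch(icer_for(set_parameter(params, up$id[i], v),
                               intervention, comparator),
                      error = function(e) NULL)
      if (is.null(cmp) || cmp$delta_qaly == 0) NA_real_
      else cmp$delta_cost / cmp$delta_qaly
    }, numeric(1))
    data.frame(parameter_id = up$id[i], low = up$low[i], high = up$high[i],
               icer_low = icers[1L], icer_high = icers[2L],
               width = if (anyNA(icers)) NA_real_ else abs(icers[2L] - icers[1L]),
               flagged = anyNA(icers))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$width, out$parameter_id, na.last = TRUE), ]
  rownames(out) <- NULL
  attr(out, "base_icer") <- base_icer
  class(out) <- c("tornado_result", "data.frame")
  out
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo propagation of parameter uncertainty: each iteration draws
#' every uncertain parameter independently from its fitted distribution
#' (Beta for probabilities and utilities, Gamma for costs; the discount
#' rate is never drawn), reruns all arms, and records costs, QALYs and
#' pairwise increments.  Draws are shared across arms for shared parameters.
#' A draw that makes an arm's conditional transition mass exceed 1 is
#' redrawn parameter-pair-wise, keeping the iteration count exact.
#'
#' @param params list with `arms` and `config`.
#' @param n_iterations number of Monte Carlo iterations.
#' @param seed RNG seed; runs are bit-reproducible.
#' @param comparisons list of `c(intervention, comparator)` pairs; defaults
#'   as in [comparison_table()].
#' @return list of class `psa_result`: `samples` (data frame, one row per
#'   iteration: `cost_<arm>`, `qaly_<arm>`, `delta_cost_<i>_vs_<c>`,
#'   `delta_qaly_<i>_vs_<c>`), `draws` (data frame of drawn parameter
#'   values), `n_redraws`, `comparisons`.
#' @export
run_psa <- function(params, n_iterations = 1000, seed = 1,
                    comparisons = NULL) {
  stopifnot(n_iterations >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  if (is.null(comparisons)) {
    nm <- names(params$arms)
    comparisons <- list()
    if (all(c("PP1M", "ER") %in% nm)) comparisons <- c(comparisons, list(c("PP1M", "ER")))
    if (all(c("PP3M", "ER") %in% nm)) comparisons <- c(comparisons, list(c("PP3M", "ER")))
  }
  up <- uncertain_parameters(params)
  up <- up[up$family %in% c("beta", "gamma"), , drop = FALSE]
  fits <- lapply(seq_len(nrow(up)), function(i)
    fit_distribution(model_param(up$mean[i], up$low[i], up$high[i],
                                 family = up$family[i])))
  names(fits) <- up$id
  n_redraws <- 0L
  draws <- matrix(NA_real_, n_iterations, nrow(up),
                  dimnames = list(NULL, up$id))
  samples <- vector("list", n_iterations)
  for (it in seq_len(n_iterations)) {
    v <- vapply(fits, draw_distribution, numeric(1))
    p_it <- params
    for (id in names(v)) p_it <- set_parameter(p_it, id, v[[id]])
    # redraw the stable-state pair for any arm whose conditional mass > 1
    for (a in names(p_it$arms)) {
      tries <- 0L
      while (p_it$arms[[a]]$p_disc_stable$value +
             p_it$arms[[a]]$p_relapse_stable$value > 1) {
        tries <- tries + 1L
        if (tries > 100L) stop("could not draw a feasible parameter set",
                               call. = FALSE)
        n_redraws <- n_redraws + 1L
        for (f in c("p_disc_stable", "p_relapse_stable")) {
          id <- paste0(a, ".", f)
          if (id %in% names(fits)) {
            v[[id]] <- draw_distribution(fits[[id]])
            p_it <- set_parameter(p_it, id, v[[id]])
          } else break
        }
      }
    }
    draws[it, ] <- v
    res <- run_all_arms(p_it)
    row <- list(iteration = it)
    for (a in names(res)) {
      row[[paste0("cost_", a)]] <- res[[a]]$total_cost
      row[[paste0("qaly_", a)]] <- res[[a]]$total_qaly
    }
    for (pr in comparisons) {
      tag <- paste0(pr[1L], "_vs_", pr[2L])
      row[[paste0("delta_cost_", tag)]] <-
        res[[pr[1L]]]$total_cost - res[[pr[2L]]]$total_cost
      row[[paste0("delta_qaly_", tag)]] <-
        res[[pr[1L]]]$total_qaly - res[[pr[2L]]]$total_qaly
    }
    samples[[it]] <- as.data.frame(row)
  }
  structure(list(samples = do.call(rbind, samples),
                 draws = as.data.frame(draws),
                 n_redraws = n_redraws,
                 comparisons = comparisons),
            class = "psa_result")
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay value, the probability that the intervention
#' is cost-effective is the fraction of PSA iterations in which its net
#' monetary benefit strictly exceeds the comparator's (ties count for the
#' comparator).  The intervention and comparator curves therefore sum to 1
#' at every grid point.
#'
#' @param psa a `psa_result` from [run_psa()].
#' @param wtp_grid vector of WTP thresholds (USD/QALY).
#' @param intervention,comparator arm names present in the PSA samples.
#' @return data frame: `wtp`, `probability` (intervention cost-effective).
#' @export
ceac <- function(psa, wtp_grid, intervention, comparator = "ER") {
  if (nrow(psa$samples) == 0L || length(wtp_grid) == 0L)
    stop("need non-empty PSA samples and WTP grid", call. = FALSE)
  s <- psa$samples
  dq <- s[[paste0("qaly_", intervention)]] - s[[paste0("qaly_", comparator)]]
  dc <- s[[paste0("cost_", intervention)]] - s[[paste0("cost_", comparator)]]
  prob <- vapply(wtp_grid, function(w) mean(w * dq - dc > 0), numeric(1))
  data.frame(wtp = wtp_grid, probability = prob)
}

#' Scenario sweeps over drug price, hospitalization cost, or time horizon
#'
#' Reruns the base-case comparisons at every grid point of one axis:
#' `price_multiplier` scales the per-cycle drug costs (all three drugs by
#' default, or only the PP formulations with `pp_only = TRUE`),
#' `hospitalization_multiplier` scales the admission cost, and
#' `horizon_years` truncates or extends the simulation.  Each default grid
#' contains the base case (multiplier 1, or the configured horizon) as a
#' consistency anchor.
#'
#' @param params list with `arms` and `config`.
#' @param axis one of `"price_multiplier"`, `"hospitalization_multiplier"`,
#'   `"horizon_years"`.
#' @param values axis grid; defaults follow the published scenarios.
#' @param pp_only for the price axis, restrict the multiplier to PP1M/PP3M.
#' @param comparisons list of `c(intervention, comparator)` pairs.
#' @return data frame of class `scenario_grid`: `axis_value` plus one ICER
#'   column per comparison; the axis name is kept in attribute `axis_name`.
#' @export
scenario_sweep <- function(params,
                           axis = c("price_multiplier",
                                    "hospitalization_multiplier",
                                    "horizon_years"),
                           values = NULL, pp_only = FALSE,
                           comparisons = list(c("PP1M", "ER"),
                                              c("PP3M", "ER"))) {
  axis <- match.arg(axis)
  if (is.null(values))
    values <- switch(axis,
      price_multiplier = c(1, 0.89, 0.8, 0.7, 0.6, 0.5, 0.4, 0.3, 0.2, 0.1),
      hospitalization_multiplier = c(1.2, 1, 0.8, 0.6, 0.4, 0.2),
      horizon_years = c(1, 5, 10, params$config$horizon_years, 30, 40))
  if (axis != "horizon_years" && any(values <= 0))
    stop("multipliers must be positive", call. = FALSE)
  run_point <- function(v) {
    p <- params
    ncyc <- NULL
    if (axis == "price_multiplier") {
      drug_arms <- if (pp_only) intersect(c("PP1M", "PP3M"), names(p$arms))
                   else names(p$arms)
      for (a in drug_arms)
        p <- set_parameter(p, paste0("cost.drug_", a),
                           params$arms[[a]]$drug_cost_cycle_stable$value * v)
    } else if (axis == "hospitalization_multiplier") {
      p <- set_parameter(p, "cost.hospitalization",
                         params$config$shared_costs$hospitalization$value * v)
    } else {
      ncyc <- as.integer(round(v * 12 / p$config$cycle_months))
    }
    vapply(comparisons, function(pr)
      icer_for(p, pr[1L], pr[2L], n_cycles = ncyc)$icer, numeric(1))
  }
  icers <- t(vapply(values, run_point,
                    numeric(length(comparisons))))
  out <- data.frame(axis_value = values)
  for (j in seq_along(comparisons))
    out[[paste0("icer_", comparisons[[j]][1L], "_vs_",
                comparisons[[j]][2L])]] <- icers[, j]
  attr(out, "axis_name") <- axis
  class(out) <- c("scenario_grid", "data.frame")
  out
}

#' Cumulative-horizon ICER series
#'
#' Reruns each comparison with the horizon truncated after 1, 2, ...,
#' `max_cycles` cycles (each truncation is a full half-cycle-corrected,
#' discounted run) and reports the ICER at every cumulative horizon.  A
#' truncation with no defined ICER is reported as `NA` and flagged.
#'
#' @param params list with `arms` and `config`.
#' @param max_cycles last cumulative cycle count (>= 1).
#' @param comparisons list of `c(intervention, comparator)` pairs.
#' @return data frame of class `scenario_grid`: `cycle` plus one ICER
#'   column and one `flagged_` column per comparison.
#' @export
icer_by_cycle <- function(params, max_cycles,
                          comparisons = list(c("PP1M", "ER"),
                                             c("PP3M", "ER"))) {
  stopifnot(max_cycles >= 1)
  out <- data.frame(cycle = seq_len(max_cycles))
  for (pr in comparisons) {
    tag <- paste0(pr[1L], "_vs_", pr[2L])
    cmps <- lapply(seq_len(max_cycles), function(k)
      icer_for(params, pr[1L], pr[2L], n_cycles = k))
    out[[paste0("icer_", tag)]] <- vapply(cmps, `[[`, numeric(1), "icer")
    out[[paste0("flagged_", tag)]] <-
      vapply(cmps, function(cm) is.na(cm$icer), logical(1))
  }
  attr(out, "axis_name") <- "cycle_count"
  class(out) <- c("scenario_grid", "data.frame")
  out
}
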