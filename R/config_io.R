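#' Serialize a parameter set to a JSON configuration file
#'
#' The schema mirrors the model's field names: each transition probability
#' carries `value`/`low`/`high`/`distribution_family`, each cost
#' `mean`/`low`/`high`/`distribution_family`/`basis` (and optionally
#' `shared_id`), each utility `per_cycle_weight`/`low`/`high`/
#' `distribution_family`, and mortality a list of
#' `age_low`/`age_high`/`annual_probability` bands.  All costs are USD, all
#' probabilities and utilities per cycle.  [parse_config()] round-trips the
#' file losslessly.
#'
#' @param params list with `arms` and `config`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(params, path) {
  prob_l <- function(p) list(value = p$value, low = p$low, high = p$high,
                             distribution_family = p$family)
  cost_l <- function(p) {
    x <- list(mean = p$value, low = p$low, high = p$high,
              distribution_family = p$family,
              basis = if (is.null(p$basis)) "per_cycle" else p$basis)
    if (!is.null(p$shared_id)) x$shared_id <- p$shared_id
    x
  }
  util_l <- function(p) list(per_cycle_weight = p$value, low = p$low,
                             high = p$high, distribution_family = p$family)
  cfg <- params$config
  doc <- list(
    arms = lapply(params$arms, function(a) {
      out <- lapply(a[arm_prob_fields()], prob_l)
      out$drug_cost_cycle_stable <- cost_l(a$drug_cost_cycle_stable)
      out$drug_cost_cycle_nonstable <- cost_l(a$drug_cost_cycle_nonstable)
      out
    }),
    config = list(
      horizon_years = cfg$horizon_years,
      cycle_months = cfg$cycle_months,
      annual_discount_rate = cfg$annual_discount_rate,
      discount_low = cfg$discount_low,
      discount_high = cfg$discount_high,
      start_age = cfg$start_age,
      wtp_per_qaly = cfg$wtp_per_qaly,
      utilities = lapply(cfg$utilities, util_l),
      shared_costs = lapply(cfg$shared_costs, cost_l),
      mortality = list(bands = lapply(seq_len(nrow(cfg$mortality)), function(i)
        list(age_low = cfg$mortality$age_low[i],
             age_high = cfg$mortality$age_high[i],
             annual_probability = cfg$mortality$annual_probability[i]))),
      relapse_hospitalization_policy = cfg$relapse_hospitalization_policy))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

check_keys <- function(x, allowed, required, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown))
    stop(sprintf("unknown key '%s' at %s", unknown[1L], where), call. = FALSE)
  missing <- setdiff(required, names(x))
  if (length(missing))
    stop(sprintf("missing required key '%s' at %s", missing[1L], where),
         call. = FALSE)
  invisible(TRUE)
}

parse_prob <- function(x, where) {
  check_keys(x, c("value", "low", "high", "distribution_family"),
             c("value"), where)
  model_param(x$value,
              low = if (is.null(x$low)) x$value else x$low,
              high = if (is.null(x$high)) x$value else x$high,
              family = if (is.null(x$distribution_family)) "fixed"
                       else x$distribution_family)
}

parse_cost <- function(x, where) {
  check_keys(x, c("mean", "low", "high", "distribution_family", "basis",
                  "shared_id"), c("mean"), where)
  model_param(x$mean,
              low = if (is.null(x$low)) x$mean else x$low,
              high = if (is.null(x$high)) x$mean else x$high,
              family = if (is.null(x$distribution_family)) "fixed"
                       else x$distribution_family,
              basis = if (is.null(x$basis)) "per_cycle" else x$basis,
              shared_id = x$shared_id)
}

parse_util <- function(x, where) {
  check_keys(x, c("per_cycle_weight", "low", "high", "distribution_family"),
             c("per_cycle_weight"), where)
  model_param(x$per_cycle_weight,
              low = if (is.null(x$low)) x$per_cycle_weight else x$low,
              high = if (is.null(x$high)) x$per_cycle_weight else x$high,
              family = if (is.null(x$distribution_family)) "fixed"
                       else x$distribution_family)
}

#' Parse and validate a JSON configuration file
#'
#' Strict schema: unknown keys are errors naming the offending key path;
#' missing optional keys take the documented defaults; the parsed set must
#' pass [validate_parameters()].
#'
#' @param path path to a file written by [write_config()] (or hand-authored
#'   to the same schema).
#' @return list with `arms` and `config`.
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  check_keys(doc, c("arms", "config"), c("arms", "config"), "top level")
  arms <- lapply(names(doc$arms), function(nm) {
    a <- doc$arms[[nm]]
    check_keys(a, c(arm_prob_fields(), "drug_cost_cycle_stable",
                    "drug_cost_cycle_nonstable"),
               c(arm_prob_fields(), "drug_cost_cycle_stable",
                 "drug_cost_cycle_nonstable"),
               paste0("arms.", nm))
    probs <- lapply(arm_prob_fields(), function(f)
      parse_prob(a[[f]], paste0("arms.", nm, ".", f)))
    names(probs) <- arm_prob_fields()
    do.call(arm_parameters, c(
      list(arm_name = nm), probs,
      list(drug_cost_cycle_stable =
             parse_cost(a$drug_cost_cycle_stable,
                        paste0("arms.", nm, ".drug_cost_cycle_stable")),
           drug_cost_cycle_nonstable =
             parse_cost(a$drug_cost_cycle_nonstable,
                        paste0("arms.", nm, ".drug_cost_cycle_nonstable")))))
  })
  names(arms) <- names(doc$arms)
  c0 <- doc$config
  check_keys(c0, c("horizon_years", "cycle_months", "annual_discount_rate",
                   "discount_low", "discount_high", "start_age",
                   "wtp_per_qaly", "utilities", "shared_costs", "mortality",
                   "relapse_hospitalization_policy"),
             c("utilities", "shared_costs", "mortality"), "config")
  check_keys(c0$utilities, c("stable", "non_stable", "relapse"),
             c("stable", "non_stable"), "config.utilities")
  utils_l <- lapply(names(c0$utilities), function(u)
    parse_util(c0$utilities[[u]], paste0("config.utilities.", u)))
  names(utils_l) <- names(c0$utilities)
  if (is.null(utils_l$relapse)) utils_l$relapse <- utils_l$non_stable
  check_keys(c0$shared_costs,
             c("hospitalization", "outpatient_stable", "outpatient_nonstable"),
             c("hospitalization", "outpatient_stable", "outpatient_nonstable"),
             "config.shared_costs")
  costs_l <- lapply(names(c0$shared_costs), function(s)
    parse_cost(c0$shared_costs[[s]], paste0("config.shared_costs.", s)))
  names(costs_l) <- names(c0$shared_costs)
  check_keys(c0$mortality, "bands", "bands", "config.mortality")
  bands <- c0$mortality$bands
  for (i in seq_along(bands))
    check_keys(bands[[i]], c("age_low", "age_high", "annual_probability"),
               c("age_low", "age_high", "annual_probability"),
               sprintf("config.mortality.bands[%d]", i))
  default <- function(key, d) if (is.null(c0[[key]])) d else c0[[key]]
  config <- model_config(
    horizon_years = default("horizon_years", 20),
    cycle_months = default("cycle_months", 3),
    annual_discount_rate = default("annual_discount_rate", 0.05),
    discount_low = default("discount_low", 0),
    discount_high = default("discount_high", 0.08),
    start_age = default("start_age", 38),
    wtp_per_qaly = default("wtp_per_qaly", 12756.55),
    utilities = utils_l,
    shared_costs = costs_l,
    mortality = mortality_table(
      age_low = vapply(bands, `[[`, numeric(1), "age_low"),
      age_high = vapply(bands, `[[`, numeric(1), "age_high"),
      annual_probability = vapply(bands, `[[`, numeric(1),
                                  "annual_probability")),
    relapse_hospitalization_policy =
      default("relapse_hospitalization_policy", "never"))
  params <- list(arms = arms, config = config)
  v <- validate_parameters(arms, config)
  if (length(v))
    stop("config failed validation: ", paste(v, collapse = "; "),
         call. = FALSE)
  params
}
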