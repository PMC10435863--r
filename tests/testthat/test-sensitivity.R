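test_that("fit_beta: method of moments recovers requested moments", {
  f <- fit_beta(0.5, 0.5 - 1.96 * sqrt(0.05), 0.5 + 1.96 * sqrt(0.05))
  expect_equal(f$alpha, 2, tolerance = 1e-10)
  expect_equal(f$beta, 2, tolerance = 1e-10)

  f2 <- fit_beta(0.0292, 0.0263, 0.0321)
  expect_equal(round(f2$sd, 7), 0.0014796)
  # analytic mean/sd of the fitted Beta equal the requested moments
  m <- f2$alpha / (f2$alpha + f2$beta)
  v <- f2$alpha * f2$beta /
    ((f2$alpha + f2$beta)^2 * (f2$alpha + f2$beta + 1))
  expect_equal(m, 0.0292, tolerance = 1e-10)
  expect_equal(sqrt(v), f2$sd, tolerance = 1e-10)

  sym <- fit_beta(0.5, 0.4, 0.6)
  expect_equal(sym$alpha, sym$beta, tolerance = 1e-12)
  expect_error(fit_beta(0.5, 0, 4), "infeasible moments")
  expect_error(fit_beta(1.2, 0.1, 0.2), "\\(0, 1\\)")
})

test_that("fit_gamma: method of moments recovers requested moments", {
  f <- fit_gamma(100, 100 - 1.96 * 20, 100 + 1.96 * 20)
  expect_equal(f$shape, 25, tolerance = 1e-10)
  expect_equal(f$scale, 4, tolerance = 1e-10)
  f2 <- fit_gamma(1998.90, 1599.12, 2398.68)
  expect_equal(round(f2$sd, 2), 203.97)
  expect_equal(f2$shape * f2$scale, 1998.90, tolerance = 1e-10)
  expect_equal(sqrt(f2$shape) * f2$scale, f2$sd, tolerance = 1e-10)
  expect_error(fit_gamma(-5, 1, 2), "positive")
})

test_that("uncertain_parameters enumerates distinct quantities with linkage", {
  up <- uncertain_parameters(ref)
  expect_setequal(
    grep("^cost\\.drug", up$id, value = TRUE),
    c("cost.drug_PP1M", "cost.drug_PP3M", "cost.drug_ER"))
  expect_true("config.annual_discount_rate" %in% up$id)
  expect_false(any(grepl("relapse$", up$id)))  # relapse utility rides non_stable

  p2 <- set_parameter(ref, "cost.drug_PP1M", 500)
  expect_equal(p2$arms$PP1M$drug_cost_cycle_stable$value, 500)
  expect_equal(p2$arms$PP1M$drug_cost_cycle_nonstable$value, 500)
  expect_equal(p2$arms$PP3M$drug_cost_cycle_nonstable$value, 500)  # linked
  expect_equal(p2$arms$PP3M$drug_cost_cycle_stable$value, 813.64)  # untouched

  p3 <- set_parameter(ref, "utility.non_stable", 0.1)
  expect_equal(p3$config$utilities$relapse$value, 0.1)
  expect_error(set_parameter(ref, "PP1M.not_a_field", 0.5), "unknown parameter")
})

test_that("tornado ranks drug costs first and is deterministically ordered", {
  for (iv in c("PP1M", "PP3M")) {
    tor <- tornado(ref, iv, "ER")
    expect_true(all(tor$width[!tor$flagged] >= 0))
    expect_false(is.unsorted(rev(tor$width[!tor$flagged])))
    # the drug billed by the intervention and the comparator's drug lead
    expect_setequal(tor$parameter_id[1:2],
                    c(paste0("cost.drug_", iv), "cost.drug_ER"))
    # every probability parameter sits below every drug cost that moves the ICER
    prob_w <- tor$width[grepl("^(PP1M|PP3M|ER)\\.", tor$parameter_id)]
    expect_lt(max(prob_w, na.rm = TRUE), tor$width[2])
    # parameters affecting neither arm leave the ICER untouched
    other <- setdiff(c("PP1M", "PP3M"), iv)
    w_other <- tor$width[tor$parameter_id == paste0(other, ".p_disc_stable")]
    expect_equal(w_other, 0, tolerance = 1e-9)
  }
  # doubling a bound's distance from the mean widens the drug-cost bar
  wide <- ref
  wide$arms$PP1M$drug_cost_cycle_stable$high <- 958.87 + 2 * (1150.65 - 958.87)
  t_base <- tornado(ref, "PP1M", "ER")
  t_wide <- tornado(wide, "PP1M", "ER")
  get_w <- function(t) t$width[t$parameter_id == "cost.drug_PP1M"]
  expect_gt(get_w(t_wide), get_w(t_base))
})

test_that("PSA is seeded, exact in count, and degenerates to the base case", {
  a <- run_psa(ref, n_iterations = 8, seed = 42)
  b <- run_psa(ref, n_iterations = 8, seed = 42)
  expect_identical(a$samples, b$samples)
  expect_equal(nrow(a$samples), 8)

  fixed <- all_fixed(ref)
  psa_fixed <- run_psa(fixed, n_iterations = 4, seed = 1)
  base <- run_all_arms(ref)
  for (arm in names(ref$arms)) {
    expect_identical(unique(psa_fixed$samples[[paste0("cost_", arm)]]),
                     base[[arm]]$total_cost)
    expect_identical(unique(psa_fixed$samples[[paste0("qaly_", arm)]]),
                     base[[arm]]$total_qaly)
  }
  expect_equal(ncol(psa_fixed$draws), 0)
})

test_that("PSA draws track their fitted distributions", {
  psa <- run_psa(ref, n_iterations = 200, seed = 3)
  up <- uncertain_parameters(ref)
  up <- up[up$family %in% c("beta", "gamma"), ]
  for (i in seq_len(nrow(up))) {
    d <- fit_distribution(model_param(up$mean[i], up$low[i], up$high[i],
                                      family = up$family[i]))
    x <- psa$draws[[up$id[i]]]
    expect_true(all(x >= 0))
    if (up$family[i] == "beta") expect_true(all(x <= 1))
    expect_lt(abs(mean(x) - d$mean), 4 * d$sd / sqrt(length(x)))
  }
})

test_that("ceac behaves at its limits and sums to one with its complement", {
  psa <- run_psa(ref, n_iterations = 60, seed = 11)
  grid <- c(0, 5000, 12756.55, 1e7)
  cc <- ceac(psa, grid, "PP1M", "ER")
  expect_true(all(cc$probability >= 0 & cc$probability <= 1))
  s <- psa$samples
  # wtp = 0: intervention wins iff strictly cheaper
  expect_equal(cc$probability[1], mean(s$cost_PP1M < s$cost_ER))
  # wtp -> large: intervention wins iff higher QALYs
  expect_equal(cc$probability[4], mean(s$qaly_PP1M > s$qaly_ER))
  # complement: reversing the comparison flips the probability
  rev_cc <- vapply(grid, function(w)
    mean(w * (s$qaly_ER - s$qaly_PP1M) - (s$cost_ER - s$cost_PP1M) > 0),
    numeric(1))
  expect_equal(cc$probability + rev_cc, rep(1, 4))
  expect_error(ceac(psa, numeric(0), "PP1M", "ER"), "non-empty")
})

test_that("ceac is identically one under universal dominance", {
  fake <- structure(list(
    samples = data.frame(iteration = 1:5,
                         cost_A = 1:5, qaly_A = 11:15,
                         cost_B = 101:105, qaly_B = 1:5),
    comparisons = list(c("A", "B"))), class = "psa_result")
  cc <- ceac(fake, c(0, 1e4, 1e6), "A", "B")
  expect_equal(cc$probability, rep(1, 3))
})

test_that("scenario sweeps anchor the base case and move monotonically", {
  base_icers <- c(
    ppcea:::icer_for(ref, "PP1M", "ER")$icer,
    ppcea:::icer_for(ref, "PP3M", "ER")$icer)

  pr <- scenario_sweep(ref, "price_multiplier")
  expect_equal(unlist(pr[pr$axis_value == 1, -1], use.names = FALSE),
               base_icers, tolerance = 1e-10)
  ok <- !is.na(pr$icer_PP1M_vs_ER)
  expect_true(all(diff(pr$icer_PP1M_vs_ER[ok]) < 0))  # cheaper drugs, lower ICER
  expect_error(scenario_sweep(ref, "price_multiplier", values = c(1, -0.2)),
               "positive")

  hosp <- scenario_sweep(ref, "hospitalization_multiplier")
  expect_equal(unlist(hosp[hosp$axis_value == 1, -1], use.names = FALSE),
               base_icers, tolerance = 1e-10)
  # costlier admissions penalize the high-hospitalization comparator:
  # ICER falls whenever the multiplier rises
  expect_true(all((hosp$icer_PP1M_vs_ER[-1] - hosp$icer_PP1M_vs_ER[-nrow(hosp)]) *
                    (hosp$axis_value[-1] - hosp$axis_value[-nrow(hosp)]) < 0))

  hz <- scenario_sweep(ref, "horizon_years")
  expect_equal(unlist(hz[hz$axis_value == 20, -1], use.names = FALSE),
               base_icers, tolerance = 1e-10)
  expect_true(all(diff(hz$icer_PP3M_vs_ER) < 0))  # longer horizon, lower ICER
})

test_that("price sweeps can target the injectables only", {
  sw <- scenario_sweep(ref, "price_multiplier", values = c(1, 0.9),
                       pp_only = TRUE)
  full <- scenario_sweep(ref, "price_multiplier", values = c(1, 0.9))
  # restricting the cut to PP drugs keeps the comparator price up,
  # so the ICER falls faster than under an across-the-board cut
  expect_lt(sw$icer_PP1M_vs_ER[2], full$icer_PP1M_vs_ER[2])
})

test_that("icer_by_cycle reproduces the full-horizon ICER at its last point", {
  ic <- icer_by_cycle(ref, n_cycles(ref$config))
  expect_equal(ic$icer_PP1M_vs_ER[n_cycles(ref$config)],
               ppcea:::icer_for(ref, "PP1M", "ER")$icer, tolerance = 1e-10)
  expect_false(any(ic$flagged_PP1M_vs_ER))
  expect_gt(ic$icer_PP1M_vs_ER[1], ic$icer_PP1M_vs_ER[n_cycles(ref$config)])
})
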