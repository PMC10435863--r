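test_that("transition matrices are row-stochastic for all arms and ages", {
  for (arm in ref$arms)
    for (age in seq(38, 90, by = 2.25)) {
      M <- build_transition_matrix(arm, ref$config, age)
      expect_true(all(abs(rowSums(M) - 1) <= 1e-12))
      expect_true(all(M >= 0 & M <= 1))
      expect_equal(unname(M["death", ]), c(0, 0, 0, 0, 1))
    }
})

test_that("matrix rows match the published complement rules at zero mortality", {
  nomort <- degenerate_fixture("no_mortality")
  M_er <- build_transition_matrix(nomort$arms$ER, nomort$config, 38)
  expect_equal(unname(M_er["non_stable", c("non_stable", "stable_adherent")]),
               c(0.2831, 1 - 0.2831), tolerance = 1e-9)
  M_pp3m <- build_transition_matrix(nomort$arms$PP3M, nomort$config, 38)
  expect_equal(unname(M_pp3m["stable_adherent",
                             c("stable_nonadherent", "relapse", "stable_adherent")]),
               c(0.0434, 0.0240, 1 - 0.0434 - 0.0240), tolerance = 1e-9)
  # relapse is a one-cycle tunnel back to non-stable
  expect_equal(unname(M_er["relapse", "non_stable"]), 1, tolerance = 1e-9)
  # infeasible conditional mass is a construction error
  bad <- ref$arms$PP1M
  bad$p_disc_stable$value <- 0.7
  bad$p_relapse_stable$value <- 0.5
  expect_error(build_transition_matrix(bad, ref$config, 38), "exceeds 1")
})

test_that("half_cycle_correct averages consecutive boundaries", {
  m <- matrix(c(1, 0.9, 0.81, 0, 0.1, 0.19), ncol = 2)
  corr <- half_cycle_correct(m)
  expect_equal(corr[, 1], c(0.95, 0.855))
  # constant memberships are unchanged; linear traces give exact midpoints
  const <- matrix(0.5, 4, 2)
  expect_equal(half_cycle_correct(const), matrix(0.5, 3, 2))
  lin <- cbind(seq(1, 0, length.out = 5), seq(0, 1, length.out = 5))
  expect_equal(half_cycle_correct(lin),
               (lin[-5, ] + lin[-1, ]) / 2)
  expect_error(half_cycle_correct(m[1, , drop = FALSE]), "two time points")
})

test_that("discount_factor uses the mid-cycle convention", {
  cfg <- ref$config
  expect_equal(round(discount_factor(1, cfg), 6), 0.993920)
  cfg0 <- cfg; cfg0$annual_discount_rate <- 0
  expect_equal(discount_factor(1:10, cfg0), rep(1, 10))
  expect_true(all(diff(discount_factor(1:80, cfg)) < 0))
})

test_that("two-cycle toy cohort matches the hand computation", {
  toy <- toy_params(2)
  out <- run_cohort(toy$arms$TOY, toy$config)
  expect_equal(out$trace$non_stable, c(1, 0.9, 0.81))
  expect_equal(out$trace$corrected_non_stable[-1], c(0.95, 0.855))
  expect_equal(out$result$total_cost, 180.50)
  expect_equal(out$result$total_qaly, 1.805)
})

test_that("zero-horizon and pinned-cohort closed forms are exact", {
  toy <- toy_params(2)
  out0 <- run_cohort(toy$arms$TOY, toy$config, n_cycles = 0)
  expect_equal(out0$result$total_cost, 0)
  expect_equal(out0$result$total_qaly, 0)

  zd <- degenerate_fixture("zero_discount")
  res <- accumulate(pinned_corrected("stable_adherent", 4), zd$arms$ER, zd$config)
  expect_equal(res$total_cost, 4 * (759.09 + 127.52))  # 3546.44
  expect_equal(res$total_qaly, 4 * 0.23)
  res2 <- accumulate(pinned_corrected("non_stable", 1), zd$arms$PP1M, zd$config)
  expect_equal(res2$total_cost, 958.87 + 183.30 + 0.0102 * 1998.90)  # 1162.56
  res3 <- accumulate(pinned_corrected("death", 8), zd$arms$PP1M, zd$config)
  expect_equal(res3$total_cost, 0)
  expect_equal(res3$total_qaly, 0)
})

test_that("totals equal their per-cycle sums and cohort mass is conserved", {
  for (arm in ref$arms) {
    out <- run_cohort(arm, ref$config)
    expect_equal(out$result$total_cost, sum(out$result$per_cycle_costs),
                 tolerance = 1e-8)
    expect_equal(out$result$total_qaly, sum(out$result$per_cycle_qalys),
                 tolerance = 1e-8)
    mass <- rowSums(out$trace[state_names()])
    expect_true(all(abs(mass - 1) <= 1e-10))
    expect_true(all(diff(out$trace$death) >= -1e-15))  # deaths non-decreasing
    expect_true(all(as.matrix(out$trace[state_names()]) >= 0))
  }
})

test_that("totals are non-increasing in the discount rate", {
  for (rate_pair in list(c(0, 0.05), c(0.05, 0.08))) {
    lo <- ref; lo$config$annual_discount_rate <- rate_pair[1]
    hi <- ref; hi$config$annual_discount_rate <- rate_pair[2]
    r_lo <- run_cohort(lo$arms$PP3M, lo$config)$result
    r_hi <- run_cohort(hi$arms$PP3M, hi$config)$result
    expect_gt(r_lo$total_cost, r_hi$total_cost)
    expect_gt(r_lo$total_qaly, r_hi$total_qaly)
  }
})

test_that("raising mortality weakly lowers total QALYs", {
  for (mult in c(2, 5)) {
    worse <- ref
    worse$config$mortality$annual_probability <-
      pmin(0.99, worse$config$mortality$annual_probability * mult)
    for (a in names(ref$arms)) {
      q_base <- run_cohort(ref$arms[[a]], ref$config)$result$total_qaly
      q_worse <- run_cohort(worse$arms[[a]], worse$config)$result$total_qaly
      expect_lt(q_worse, q_base)
    }
  }
})

test_that("microsimulation oracle is seeded and agrees with the cohort engine", {
  a <- microsim_oracle(ref$arms$PP3M, ref$config, 500, seed = 99)
  b <- microsim_oracle(ref$arms$PP3M, ref$config, 500, seed = 99)
  expect_identical(a, b)

  ms <- microsim_oracle(ref$arms$PP3M, ref$config, 20000, seed = 7)
  co <- run_cohort(ref$arms$PP3M, ref$config)$result
  expect_lt(abs(ms$total_cost - co$total_cost), 3 * ms$se_cost)
  expect_lt(abs(ms$total_qaly - co$total_qaly), 3 * ms$se_qaly)
})

test_that("forced absorption kills every trajectory after one cycle", {
  dead <- degenerate_fixture("immediate_death")
  ms <- microsim_oracle(dead$arms$ER, dead$config, 200, seed = 1)
  # everyone spends cycle 1 half-alive in non-stable, then nothing accrues
  cost_ns <- state_costs(dead$arms$ER, dead$config)[["non_stable"]]
  util_ns <- state_utilities(dead$config)[["non_stable"]]
  df1 <- discount_factor(1, dead$config)
  expect_equal(ms$total_cost, cost_ns / 2 * df1, tolerance = 1e-6)
  expect_equal(ms$total_qaly, util_ns / 2 * df1, tolerance = 1e-6)
})
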