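test_that("probit generation matches the closed-form prevalences", {
  scn <- scenario_preset(row = 1)
  scn$n_per_arm <- 20000L
  td <- generate_on_treatment(scn, seed = 90)
  for (arm in c("active", "reference")) {
    mu <- if (arm == "active") scn$mu_a else scn$mu_r
    for (j in 1:2) {
      prev <- mean(td$y[td$arm == arm, j])
      truth <- pnorm(-mu[j])
      se <- sqrt(truth * (1 - truth) / scn$n_per_arm)
      expect_lt(abs(prev - truth), 3 * se)
    }
  }
  # latents decode to the binary outcomes by the sign rule
  z <- attr(td, "latent")
  expect_identical(td$y, trial_data((z <= 0) * 1, td$arm, td$id)$y)
  # extreme mean drives the prevalence to zero
  scn0 <- scenario(c(1.57, 50), c(1.57, 50), matrix(c(1, .6, .6, 1), 2),
                   n_per_arm = 500)
  expect_equal(mean(generate_on_treatment(scn0, seed = 91)$y[, 2]), 0)
  # determinism
  expect_identical(generate_on_treatment(scn, seed = 90)$y, td$y)
})

test_that("deviation follows the logistic mechanism with monotone forcing", {
  scn <- scenario_preset(row = 1, missing = "30")
  scn$n_per_arm <- 20000L
  td <- generate_on_treatment(scn, seed = 92)
  # closed-form deviation fraction given the baseline outcome
  d <- impose_deviation(td, scn, seed = 93)
  act <- td$arm == "active"
  for (y1 in 0:1) {
    rows <- act & td$y[, 1] == y1
    expect_gt(sum(rows), 300)
    frac <- mean(d[rows] < 2)
    truth <- 1 - plogis(0.367 + 0.032 + 1.167 * y1)
    se <- sqrt(truth * (1 - truth) / sum(rows))
    expect_lt(abs(frac - truth), 3.5 * se)
  }
  # reference arm untouched when no mechanism is given
  expect_true(all(d[td$arm == "reference"] == 2))
  # an overwhelming intercept removes deviation entirely
  scn_no <- scn
  scn_no$dev_active <- list(deviation_mechanism(2L, 50, 1.167))
  expect_true(all(impose_deviation(td, scn_no, seed = 94) == 2))

  # three-visit design: deviation at time 2 forces deviation at time 3
  scn3 <- scenario_preset(row = 1, followups = 3, missing = "30")
  scn3$n_per_arm <- 4000L
  td3 <- generate_on_treatment(scn3, seed = 95)
  d3 <- impose_deviation(td3, scn3, seed = 96)
  expect_true(all(d3 %in% 1:3))
  masked3 <- mask_post_deviation(td3, d3)
  expect_true(validate_trial(masked3)$pass)   # monotone by construction
})

test_that("truth regeneration preserves completers and the MAR law", {
  scn <- scenario_preset(row = 1, missing = "30", truth = "CR")
  scn$n_per_arm <- 30000L
  td <- generate_on_treatment(scn, seed = 97)
  d <- impose_deviation(td, scn, seed = 98)
  regen_mar <- regenerate_post_deviation(td, d, "MAR", scn, seed = 99)
  # completers byte-identical
  comp <- d == 2
  expect_identical(regen_mar$y[comp, ], td$y[comp, ])
  # MAR regeneration leaves the marginal prevalence unchanged
  act <- td$arm == "active"
  p0 <- pnorm(0.13)
  se <- sqrt(p0 * (1 - p0) / sum(act))
  expect_lt(abs(mean(regen_mar$y[act, 2]) - p0), 3 * se)
  # CR truth: reference-arm patients always regenerated under MAR, so the
  # reference arm's law is unchanged
  regen_cr <- regenerate_post_deviation(td, d, "CR", scn, seed = 100)
  ref <- td$arm == "reference"
  expect_identical(regen_cr$y[ref, ], regenerate_post_deviation(
    td, d, "MAR", scn, seed = 100)$y[ref, ])
  # active-arm deviators move toward the reference prevalence under CR
  dev_act <- act & d < 2
  expect_lt(mean(regen_cr$y[dev_act, 2]), mean(regen_mar$y[dev_act, 2]))
})

test_that("CR, J2R and CIR truths coincide when baseline means are equal", {
  scn <- scenario_preset(row = 1, missing = "30")
  scn$n_per_arm <- 2000L
  td <- generate_on_treatment(scn, seed = 101)
  d <- impose_deviation(td, scn, seed = 102)
  outs <- lapply(c("CR", "J2R", "CIR"), function(tr) {
    regenerate_post_deviation(td, d, tr, scn, seed = 103)$y
  })
  expect_identical(outs[[1]], outs[[2]])
  expect_identical(outs[[1]], outs[[3]])
})

test_that("the large-sample true value matches the closed form under MAR", {
  scn <- scenario_preset(row = 1, missing = "30", truth = "MAR")
  lor <- compute_true_log_or(scn, "MAR", n = 3e5, seed = 104)
  closed <- log((pnorm(0.13) / pnorm(-0.13)) / (pnorm(-0.26) / pnorm(0.26)))
  expect_equal(closed, 0.6238, tolerance = 1e-4)
  # binomial Monte-Carlo bound on the simulated value
  expect_lt(abs(lor - closed), 4 * sqrt(4 / (3e5 * 0.4)))
  # two independent approximations agree within their joint error bound
  lor2 <- compute_true_log_or(scn, "MAR", n = 2e5, seed = 105)
  expect_lt(abs(lor - lor2), 4 * sqrt(4 / (2e5 * 0.4)))
})

test_that("anchored variance and MCSE implement the stated formulas", {
  expect_equal(anchored_variance(0.2, 0.1, 0.15), 0.3)
  expect_equal(anchored_variance(0.37, 0.37, 0.123), 0.123)
  # the anchored inflation factor equals the MAR inflation factor exactly
  v_obs <- 0.21; v_full <- 0.17; v_ref <- 0.19
  expect_equal(anchored_variance(v_obs, v_full, v_ref) / v_ref, v_obs / v_full)
  expect_error(anchored_variance(-1, 1, 1))
  expect_equal(mcse(0.126, 1000), sqrt(0.126 / 1000))
  expect_equal(mcse(0, 10), 0)
})

test_that("a zero-deviation scenario shows no bias and full-data variance", {
  scn <- scenario_preset(row = 1)
  scn$dev_active <- list(deviation_mechanism(2L, 50, 0))  # nobody deviates
  scn$truth <- "MAR"
  perf <- run_scenario(scn, methods = "latent", assumptions = "MAR",
                       n_sim = 25, K = 3, config = quick_config(3),
                       n_true = 1e5, seed = 106)
  expect_equal(perf$mean_model_var, perf$mean_v_full, tolerance = 0.02)
  expect_lt(abs(perf$bias), 3 * perf$mcse)
  expect_equal(perf$n_sim, 25L)
  expect_equal(perf$anchored_var, perf$mean_v_full_reference, tolerance = 0.02)
})

test_that("scenario configuration validates its inputs", {
  expect_error(scenario(c(0, 1), c(0, 1, 2), diag(2)))
  expect_error(scenario(c(0, 1), c(0, 1), matrix(c(2, 0, 0, 1), 2)))
  expect_error(scenario_preset(row = 6), "row")
  s <- scenario_preset(row = 4, followups = 3, missing = "5", both_arms = TRUE)
  expect_length(s$mu_r, 3)
  expect_length(s$dev_reference, 2)
})
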