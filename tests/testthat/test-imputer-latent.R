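test_that("latent refresh respects the sign convention and half-normal moments", {
  om <- diag(1)
  set.seed(60)
  # Y = 1 => Z <= 0; with mu = 0 the draws are half-normal with mean -sqrt(2/pi)
  z1 <- replicate(4000, sample_latent_given_binary(0, om, 1, 0))
  expect_true(all(z1 <= 0))
  expect_equal(mean(z1), -sqrt(2 / pi), tolerance = 0.03)
  # Y = 0 => Z > 0
  z0 <- replicate(500, sample_latent_given_binary(0, om, 0, 0))
  expect_true(all(z0 > 0))
  # missing Y: unconstrained conditional (moment check)
  zm <- replicate(4000, sample_latent_given_binary(0.4, om, NA, 0))
  expect_equal(mean(zm), 0.4, tolerance = 0.06)
  expect_equal(sd(zm), 1, tolerance = 0.05)
})

test_that("Metropolis correlation update recovers a known correlation", {
  # zero proposal scale leaves omega unchanged
  set.seed(61)
  z <- matrix(rnorm(200), 100, 2)
  om <- matrix(c(1, .3, .3, 1), 2)
  expect_identical(mh_update_correlation(om, z, c(0, 0), 0)$omega, om)

  # posterior concentration around the true latent correlation
  n <- 2000
  z <- matrix(rnorm(2 * n), n, 2) %*% chol(matrix(c(1, .6, .6, 1), 2))
  om <- diag(2)
  kept <- numeric(2000)
  for (i in 1:2000) {
    om <- mh_update_correlation(om, z, c(0, 0), 0.05)$omega
    kept[i] <- om[1, 2]
  }
  expect_lt(abs(mean(kept[501:2000]) - 0.6), 0.05)
  # proposals breaking |r| < 1 or positive definiteness never stick
  expect_true(all(abs(kept) < 1))
})

test_that("latent Gibbs fit recovers probit means and correlation", {
  set.seed(62)
  # one visit, prevalence 1/2 => mu ~ 0
  y1 <- matrix(rbinom(1000, 1, 0.5), ncol = 1)
  cfg <- sampler_config(n_draws = 50, burn_in = 100, thin = 5)
  d1 <- gibbs_latent_fit(y1, cfg)
  expect_lt(abs(mean(sapply(d1, `[[`, "mu"))), 0.12)

  # one visit, prevalence ~ Phi(-1) = 0.1587 => mu ~ +1 under Z<=0 <=> Y=1
  y2 <- matrix(rbinom(2000, 1, pnorm(-1)), ncol = 1)
  d2 <- gibbs_latent_fit(y2, cfg)
  mu_hat <- mean(sapply(d2, `[[`, "mu"))
  mle <- qnorm(1 - mean(y2))
  expect_lt(abs(mu_hat - mle), 0.08)

  # two visits from the common-prevalence reference-arm generating model
  scn <- scenario_preset(row = 1)
  scn$n_per_arm <- 2000L
  td <- generate_on_treatment(scn, seed = 63)
  yr <- td$y[td$arm == "reference", ]
  d3 <- gibbs_latent_fit(yr, sampler_config(n_draws = 60, burn_in = 300, thin = 10))
  mus <- t(sapply(d3, `[[`, "mu"))
  oms <- sapply(d3, function(d) d$omega[1, 2])
  expect_lt(max(abs(colMeans(mus) - c(1.57, 0.26))), 0.1)
  expect_lt(abs(mean(oms) - 0.6), 0.07)
  # unit diagonal preserved exactly in every retained draw
  for (d in d3) expect_identical(unname(diag(d$omega)), c(1, 1))
})

test_that("cpp and R latent engines produce identical seeded draws", {
  set.seed(64)
  y <- matrix(rbinom(120, 1, 0.4), 40, 3)
  y[1:10, 3] <- NA; y[1:4, 2:3] <- NA
  cfg <- sampler_config(n_draws = 3, burn_in = 55, thin = 4, seed = 65)
  a <- gibbs_latent_fit(y, cfg, engine = "cpp")
  b <- gibbs_latent_fit(y, cfg, engine = "r")
  for (k in 1:3) {
    expect_equal(a[[k]]$mu, b[[k]]$mu, tolerance = 1e-12)
    expect_equal(a[[k]]$omega, b[[k]]$omega, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("sequential draws decode observed outcomes exactly", {
  set.seed(66)
  mu <- c(0.3, -0.2, 0.4)
  om <- matrix(c(1, .5, .4, .5, 1, .6, .4, .6, 1), 3)
  joint <- build_joint("MAR", "active", mu, om, mu, om, 3)
  for (rep in 1:20) {
    y_row <- rbinom(3, 1, 0.5)
    out <- sequential_reference_draw(joint, y_row)
    expect_identical(out$y, as.numeric(y_row))       # completer reproduced
    expect_true(all((out$z <= 0) == (y_row == 1)))   # sign consistency
  }
  # deviating patient: observed prefix reproduced, missing decoded by sign
  joint2 <- build_joint("J2R", "active", mu, om, c(0, 0, 0), om, 1)
  out <- sequential_reference_draw(joint2, c(1, NA, NA))
  expect_equal(out$y[1], 1)
  expect_true(all(out$y %in% c(0, 1)))
})

test_that("the J2R two-visit conditional matches the worked form", {
  # the latent conditional for visit 2 under J2R must be
  # N(mu_r2 + (z1 - mu_a1) * s_r12 / s_r11, 1 - s_r12^2 / s_r11)
  mu_a <- c(0.8, -0.1); mu_r <- c(1.2, 0.5)
  om_a <- matrix(c(1, .3, .3, 1), 2); om_r <- matrix(c(1, .62, .62, 1), 2)
  joint <- build_joint("J2R", "active", mu_a, om_a, mu_r, om_r, 1)
  set.seed(67)
  outs <- replicate(6000, sequential_reference_draw(joint, c(0, NA))$z)
  z1 <- outs[1, ]; z2 <- outs[2, ]
  resid <- z2 - (mu_r[2] + (z1 - mu_a[1]) * om_r[1, 2])
  expect_equal(mean(resid), 0, tolerance = 0.035)
  expect_equal(var(resid), 1 - om_r[1, 2]^2, tolerance = 0.035)
})

test_that("truncated fast path and rejection loop agree in distribution", {
  mu <- c(0.4, 0.1)
  om <- matrix(c(1, .55, .55, 1), 2)
  joint <- build_joint("MAR", "active", mu, om, mu, om, 1)
  y <- matrix(c(1, NA), nrow = 1)[rep(1, 20000), ]
  set.seed(68)
  zt <- binrefmi:::draw_sequential_group(joint, y, method = "truncated")$z
  zr <- binrefmi:::draw_sequential_group(joint, y, method = "rejection")$z
  expect_gt(suppressWarnings(ks.test(zt[, 1], zr[, 1]))$p.value, 0.01)
  expect_gt(suppressWarnings(ks.test(zt[, 2], zr[, 2]))$p.value, 0.01)
})

test_that("a vanishing acceptance region aborts instead of looping", {
  joint <- build_joint("MAR", "active", c(12, 0), diag(2), c(12, 0), diag(2), 1)
  # observed Y = 1 demands Z <= 0 while the conditional sits at +12 sd
  expect_error(sequential_reference_draw(joint, c(1, NA)),
               "degenerate acceptance region")
})

test_that("latent imputation is deterministic and leaves observed cells alone", {
  scn <- scenario_preset(row = 1)
  data <- generate_on_treatment(scn, seed = 69)
  masked <- mask_post_deviation(data, impose_deviation(data, scn, seed = 70))
  a <- impute_latent(masked, "CR", K = 3, config = quick_config(3), seed = 71)
  b <- impute_latent(masked, "CR", K = 3, config = quick_config(3), seed = 71)
  expect_identical(a$completions, b$completions)
  obs <- !is.na(masked$y)
  for (k in 1:3) {
    expect_identical(a$completions[[k]][obs], masked$y[obs])
    expect_true(all(a$completions[[k]] %in% c(0, 1)))
  }
  # complete data round-trips untouched
  stack <- impute_latent(data, "J2R", K = 2, config = quick_config(2), seed = 72)
  expect_identical(stack$completions[[1]], data$y)
})

test_that("retained draws are effectively independent at the thinning used", {
  # autocorrelation of the retained mean components at spacings 100 and 500
  scn <- scenario_preset(row = 1)
  td <- generate_on_treatment(scn, seed = 73)
  ya <- td$y[td$arm == "active", ]
  ya[1:90, 2] <- NA
  for (spacing in c(100L, 500L)) {
    dr <- gibbs_latent_fit(ya, sampler_config(n_draws = 600, burn_in = 500,
                                              thin = spacing, seed = 74))
    mus <- t(sapply(dr, `[[`, "mu"))
    for (j in 1:2) {
      ac <- stats::acf(mus[, j], lag.max = 1, plot = FALSE)$acf[2]
      expect_lt(abs(ac), 0.1)
    }
  }
})
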