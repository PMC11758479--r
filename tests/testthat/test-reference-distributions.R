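test_that("sigma_j2r reproduces hand-computed block algebra", {
  # identical arms: the constraints are satisfied by the common matrix itself
  s <- matrix(c(1, .6, .6, 1), 2)
  expect_equal(sigma_j2r(s, s, 1), s)
  expect_equal(sigma_j2r(matrix(c(1, .4, .4, 1), 2), s, 1), s)
  # different pre-deviation variance in the active arm
  out <- sigma_j2r(matrix(c(2, .4, .4, 1), 2), s, 1)
  expect_equal(out, matrix(c(2, 1.2, 1.2, 1.36), 2))
  expect_error(sigma_j2r(matrix(c(1, 2, 2, 1), 2), s, 1), "positive definite")
})

test_that("sigma_j2r satisfies all three constraints on random PD inputs", {
  set.seed(30)
  for (rep in 1:25) {
    p <- sample(2:4, 1)
    d <- sample(seq_len(p - 1), 1)
    A <- random_pd(p); R <- random_pd(p)
    S <- sigma_j2r(A, R, d)
    pre <- seq_len(d); post <- seq.int(d + 1, p)
    expect_equal(S[pre, pre, drop = FALSE], A[pre, pre, drop = FALSE], tolerance = 1e-12)
    expect_equal(S[post, pre, drop = FALSE] %*% solve(S[pre, pre, drop = FALSE]),
                 R[post, pre, drop = FALSE] %*% solve(R[pre, pre, drop = FALSE]), tolerance = 1e-10)
    expect_equal(S[post, post, drop = FALSE] - S[post, pre, drop = FALSE] %*% solve(S[pre, pre, drop = FALSE], S[pre, post, drop = FALSE]),
                 R[post, post, drop = FALSE] - R[post, pre, drop = FALSE] %*% solve(R[pre, pre, drop = FALSE], R[pre, post, drop = FALSE]),
                 tolerance = 1e-10)
    expect_true(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) > 0)
  }
})

test_that("build_joint implements each assumption's mean construction", {
  mu_a <- c(1, 2, 3); mu_r <- c(0, 1, 4)
  sa <- random_pd(3); sr <- random_pd(3)
  # MAR: own-arm parameters unchanged for any d
  for (d in 1:3) {
    j <- build_joint("MAR", "active", mu_a, sa, mu_r, sr, d)
    expect_equal(j$mu_star, mu_a)
    expect_equal(j$sigma_star, unname(sa))
  }
  # J2R: own means to d, reference means after
  expect_equal(build_joint("J2R", "active", mu_a, sa, mu_r, sr, 2)$mu_star,
               c(1, 2, 4))
  # CR: reference means throughout, J2R covariance
  jcr <- build_joint("CR", "active", mu_a, sa, mu_r, sr, 2)
  expect_equal(jcr$mu_star, mu_r)
  expect_equal(jcr$sigma_star, sigma_j2r(sa, sr, 2))
  # CIR: increments of the reference arm continued from the own-arm mean
  expect_equal(build_joint("CIR", "active", mu_a, sa, mu_r, sr, 2)$mu_star,
               c(1, 2, 2 + 4 - 1))
  # LMCF: own-arm mean frozen at the deviation visit
  expect_equal(build_joint("LMCF", "active", mu_a, sa, mu_r, sr, 2)$mu_star,
               c(1, 2, 2))
  expect_error(build_joint("J3R", "active", mu_a, sa, mu_r, sr, 2), "unknown assumption")
})

test_that("reference-arm patients and completers reduce to MAR", {
  mu_a <- c(1, 2); mu_r <- c(0, 1)
  sa <- matrix(c(1, .3, .3, 1), 2); sr <- matrix(c(1, .7, .7, 1), 2)
  for (assum in c("J2R", "CR", "CIR")) {
    j <- build_joint(assum, "reference", mu_a, sa, mu_r, sr, 1)
    expect_equal(j$mu_star, mu_r)
    expect_equal(j$sigma_star, sr)
  }
  # completer: empty post block, own-arm joint
  j <- build_joint("CR", "active", mu_a, sa, mu_r, sr, 2)
  expect_equal(j$mu_star, mu_a)
  cond <- condition_on_observed(j, c(1, 0))
  expect_length(cond$mean, 0)
})

test_that("conditioning matches the Schur complement and the worked J2R case", {
  # zero cross-covariance: conditional equals the marginal post block
  j <- build_joint("MAR", "active", c(1, 2), diag(2), c(0, 0), diag(2), 1)
  cond <- condition_on_observed(j, 5)
  expect_equal(cond$mean, 2)
  expect_equal(cond$cov, matrix(1))
  # hand Schur complement
  j <- build_joint("MAR", "active", c(0, 0), matrix(c(1, .6, .6, 1), 2),
                   c(0, 0), diag(2), 1)
  cond <- condition_on_observed(j, 1)
  expect_equal(cond$mean, 0.6)
  expect_equal(cond$cov, matrix(0.64))
  # J2R with J+1 = 2: N(mu_r2 + (z - mu_a1) s_r12 / s_r11, 1 - s_r12^2 / s_r11)
  mu_a <- c(0.9, 0.1); mu_r <- c(1.4, 0.3)
  sr <- matrix(c(1, .55, .55, 1), 2)
  j <- build_joint("J2R", "active", mu_a, diag(2), mu_r, sr, 1)
  z1 <- 0.25
  cond <- condition_on_observed(j, z1)
  expect_equal(cond$mean, mu_r[2] + (z1 - mu_a[1]) * sr[1, 2] / sr[1, 1])
  expect_equal(cond$cov[1, 1], 1 - sr[1, 2]^2 / sr[1, 1])
})

test_that("equal pre-deviation means make J2R, CR and CIR conditionals coincide", {
  set.seed(31)
  for (rep in 1:10) {
    p <- sample(2:4, 1); d <- sample(seq_len(p - 1), 1)
    mu_r <- rnorm(p)
    mu_a <- mu_r
    mu_a[seq.int(d + 1, p)] <- rnorm(p - d)   # only post-deviation means differ
    sa <- random_pd(p); sr <- random_pd(p)
    obs <- rnorm(d)
    conds <- lapply(c("J2R", "CR", "CIR"), function(a) {
      condition_on_observed(build_joint(a, "active", mu_a, sa, mu_r, sr, d), obs)
    })
    expect_identical(conds[[1]]$mean, conds[[2]]$mean)
    expect_identical(conds[[1]]$mean, conds[[3]]$mean)
    expect_equal(conds[[1]]$cov, conds[[2]]$cov, tolerance = 1e-12)
    expect_equal(conds[[1]]$cov, conds[[3]]$cov, tolerance = 1e-12)
  }
})

test_that("joints are positive definite for every assumption", {
  set.seed(32)
  for (rep in 1:10) {
    p <- sample(2:4, 1); d <- sample(seq_len(p - 1), 1)
    sa <- random_pd(p); sr <- random_pd(p)
    for (a in c("MAR", "J2R", "CR", "CIR", "LMCF")) {
      j <- build_joint(a, "active", rnorm(p), sa, rnorm(p), sr, d)
      ev <- eigen(j$sigma_star, symmetric = TRUE, only.values = TRUE)$values
      expect_true(min(ev) > 0)
    }
  }
})
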