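# Shared fixtures: all built in code at test time.

# small monotone trial: 3 visits, mixed deviation times
toy_trial <- function() {
  y <- rbind(c(1, 0, 1),    # completer
             c(0, 1, NA),   # d = 2
             c(0, NA, NA),  # d = 1
             c(1, 1, 0),
             c(0, 0, NA),
             c(1, NA, NA))
  trial_data(y, rep(c("active", "reference"), each = 3),
             id = paste0("p", 1:6))
}

# random correlation/covariance matrices through a factor construction
random_pd <- function(p, unit_diag = FALSE) {
  a <- matrix(stats::rnorm(p * (p + 2)), p + 2, p)
  s <- crossprod(a) / (p + 2) + diag(1e-3, p)
  if (unit_diag) s <- stats::cov2cor(s)
  s
}

# fast sampler settings for unit tests (not the package defaults)
quick_config <- function(K = 5L) sampler_config(n_draws = K, burn_in = 50L, thin = 5L)

# deterministic complete binary trial of a given size
complete_trial <- function(n_per_arm = 40L, p = 2L, seed = 1L) {
  scn <- scenario_preset(row = 1, followups = if (p == 2L) 1L else 3L)
  generate_on_treatment(scn, seed = seed)
}
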