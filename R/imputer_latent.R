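# Method 2: latent multivariate normal (multivariate probit) imputation.
# Each binary outcome is the sign indicator of a unit-variance latent normal:
# Z > 0 <=> Y = 0 and Z <= 0 <=> Y = 1, with per-arm latent means and a
# correlation matrix estimated by a Gibbs sampler with element-wise
# Metropolis updates of the correlations.

trunc_interval <- function(yval) {
  # probability bounds (plo, phi) on the standard uniform scale for a latent
  # value consistent with the observed binary outcome
  if (is.na(yval)) c(0, 1) else if (yval == 0) c(NA, 1) else c(0, NA)
}

# Vectorized inverse-CDF truncated normal draw: yv in {0,1,NA} per element.
trunc_draw_vec <- function(cm, s, yv, u) {
  pz <- stats::pnorm(-cm / s)    # P(z <= 0 | conditional)
  plo <- ifelse(!is.na(yv) & yv == 0, pz, 0)
  phi <- ifelse(!is.na(yv) & yv == 1, pz, 1)
  q <- pmin(pmax(plo + u * (phi - plo), 1e-16), 1 - 1e-16)
  cm + s * stats::qnorm(q)
}

#' Refresh one patient's latent values given the binary outcomes
#'
#' Redraws each latent coordinate from its full conditional normal given the
#' other coordinates, truncated to `(0, Inf)` where the observed outcome is 0,
#' to `(-Inf, 0]` where it is 1, and unrestricted where the outcome is
#' missing. One sweep of the within-patient step of the latent Gibbs sampler.
#'
#' @param mu Latent mean vector.
#' @param omega Latent correlation matrix (unit diagonal, positive definite).
#' @param y_row Binary outcomes (0/1/NA) for the patient.
#' @param z_row Current latent values.
#' @return Updated latent vector, sign-consistent with `y_row`.
#' @export
sample_latent_given_binary <- function(mu, omega, y_row, z_row) {
  p <- length(mu)
  stopifnot(length(y_row) == p, length(z_row) == p,
            isTRUE(all.equal(diag(omega), rep(1, p))))
  for (j in seq_len(p)) {
    rest <- setdiff(seq_len(p), j)
    if (length(rest)) {
      w <- solve(omega[rest, rest, drop = FALSE], omega[rest, j])
      v <- max(1 - sum(omega[j, rest] * w), 1e-12)
      cm <- mu[j] + sum(w * (z_row[rest] - mu[rest]))
    } else {
      v <- 1; cm <- mu[j]
    }
    z_row[j] <- trunc_draw_vec(cm, sqrt(v), y_row[j], stats::runif(1))
  }
  z_row
}

#' One Metropolis sweep over the latent correlation matrix
#'
#' Proposes a symmetric Gaussian random-walk step for each off-diagonal
#' element in turn, accepting by the multivariate normal likelihood ratio of
#' the current latent matrix under a flat prior restricted to positive
#' definite matrices with unit diagonal. Proposals that break positive
#' definiteness (or reach `|r| >= 1`) are rejected; the diagonal never
#' changes.
#'
#' @param omega Current correlation matrix.
#' @param z Latent data matrix (patients by visits).
#' @param mu Latent mean vector.
#' @param proposal_sd Random-walk standard deviation (scalar or matrix).
#' @return List with `omega`, `accepted` (count) and `attempted`.
#' @export
mh_update_correlation <- function(omega, z, mu, proposal_sd) {
  p <- ncol(omega)
  n <- nrow(z)
  if (length(proposal_sd) == 1L) proposal_sd <- matrix(proposal_sd, p, p)
  zc <- sweep(z, 2L, mu)
  S <- crossprod(zc)
  ch <- chol(omega)
  logdet <- 2 * sum(log(diag(ch)))
  Oinv <- chol2inv(ch)
  accepted <- 0L; attempted <- 0L
  acc_mat <- matrix(0, p, p)
  for (k in seq_len(p)[-1L]) {
    for (j in seq_len(k - 1L)) {
      attempted <- attempted + 1L
      step <- stats::rnorm(1) * proposal_sd[j, k]
      if (step == 0) next
      rp <- omega[j, k] + step
      if (abs(rp) >= 0.9999) next
      omp <- omega
      omp[j, k] <- omp[k, j] <- rp
      chp <- chol_or_null(omp)
      if (is.null(chp)) next
      logdet_p <- 2 * sum(log(diag(chp)))
      Oinv_p <- chol2inv(chp)
      delta <- -0.5 * n * (logdet_p - logdet) -
        0.5 * (sum(Oinv_p * S) - sum(Oinv * S))
      if (log(stats::runif(1)) < delta) {
        omega <- omp; logdet <- logdet_p; Oinv <- Oinv_p
        accepted <- accepted + 1L
        acc_mat[j, k] <- acc_mat[j, k] + 1
      }
    }
  }
  list(omega = omega, accepted = accepted, attempted = attempted,
       accept_matrix = acc_mat)
}

# R reference engine for the latent Gibbs sampler; mirrors cpp_latent_gibbs
# in its RNG consumption so seeded runs agree across engines.
latent_gibbs_r <- function(y, burn_in, thin, n_draws, prop_sd = 0.1, adapt = TRUE) {
  n <- nrow(y); p <- ncol(y)
  z <- matrix(0, n, p)
  mu <- rep(0, p)
  Om <- diag(p)
  sd_m <- matrix(prop_sd, p, p)
  acc_win <- att_win <- matrix(0, p, p)
  draws <- vector("list", n_draws); got <- 0L
  total <- burn_in + (n_draws - 1L) * thin + 1L
  for (t in seq_len(total)) {
    for (j in seq_len(p)) {
      rest <- setdiff(seq_len(p), j)
      w <- solve(Om[rest, rest, drop = FALSE], Om[rest, j])
      v <- max(1 - sum(Om[j, rest] * w), 1e-12)
      cm <- mu[j] + drop(sweep(z[, rest, drop = FALSE], 2L, mu[rest]) %*% w)
      u <- stats::runif(n)
      z[, j] <- trunc_draw_vec(cm, sqrt(v), y[, j], u)
    }
    mu <- colMeans(z) + drop(t(chol(Om)) %*% stats::rnorm(p)) / sqrt(n)
    upd <- mh_update_correlation(Om, z, mu, sd_m)
    Om <- upd$omega
    # per-element window counters for burn-in adaptation (each off-diagonal
    # element is attempted exactly once per sweep)
    acc_win <- acc_win + upd$accept_matrix
    att_win <- att_win + upper.tri(att_win)
    if (adapt && t <= burn_in && t %% 50L == 0L) {
      rate <- acc_win / pmax(att_win, 1)
      grow <- upper.tri(rate) & rate > 0.5
      shrink <- upper.tri(rate) & rate < 0.35
      sd_m[grow] <- sd_m[grow] * 1.25
      sd_m[shrink] <- sd_m[shrink] * 0.8
      acc_win[] <- 0; att_win[] <- 0
    }
    if (t > burn_in && (t - burn_in - 1L) %% thin == 0L && got < n_draws) {
      got <- got + 1L
      draws[[got]] <- list(mu = mu, omega = sym(Om))
    }
  }
  draws
}

#' Fit the latent-normal model to one arm by Gibbs sampling
#'
#' Alternates (i) refreshing the latent matrix from truncated full
#' conditionals, (ii) drawing the latent means from their normal full
#' conditional under a flat prior, and (iii) element-wise Metropolis updates
#' of the correlation matrix (unit diagonal, flat prior on the positive
#' definite region). Starts from zero means, the identity correlation matrix
#' and zero latents. The proposal scale (initial sd 0.1) adapts toward a
#' 35--50% acceptance rate during burn-in and is frozen afterwards.
#'
#' @param y Binary outcome matrix for one arm (0/1/`NA`).
#' @param config A [sampler_config()].
#' @param engine `"cpp"` (default) or `"r"` (reference implementation).
#' @param prop_sd Initial Metropolis proposal standard deviation.
#' @param adapt Adapt the proposal scale during burn-in.
#' @return List of `n_draws` draws, each a list with `mu` and `omega`, with
#'   attributes `accept_rate` and `prop_sd` (cpp engine).
#' @export
gibbs_latent_fit <- function(y, config = sampler_config(), engine = c("cpp", "r"),
                             prop_sd = 0.1, adapt = TRUE) {
  engine <- match.arg(engine)
  y <- as.matrix(y)
  n <- nrow(y); p <- ncol(y)
  set_seed_if(config$seed)
  const_col <- apply(y, 2L, function(col) {
    obs <- col[!is.na(col)]
    length(obs) > 0L && (all(obs == 0) || all(obs == 1))
  })
  if (any(const_col)) {
    warning("all-constant binary column(s) ", paste(which(const_col), collapse = ", "),
            ": latent mean weakly identified", call. = FALSE)
  }
  if (engine == "cpp") {
    yi <- y
    storage.mode(yi) <- "integer"
    out <- cpp_latent_gibbs(yi, config$burn_in, config$thin, config$n_draws,
                            prop_sd, adapt)
    draws <- lapply(seq_len(config$n_draws), function(k) {
      list(mu = drop(out$mu[k, ]), omega = out$omega[[k]])
    })
    attr(draws, "accept_rate") <- out$accept_rate
    attr(draws, "prop_sd") <- out$prop_sd
    draws
  } else {
    latent_gibbs_r(y, config$burn_in, config$thin, config$n_draws, prop_sd, adapt)
  }
}

# Sequential reference-based latent draw for a group of patients sharing the
# same arm and deviation time. Visits are processed in order; at each visit
# the latent value is drawn from its conditional given previously accepted
# latents, constrained to the sign-consistent region where the outcome is
# observed, and decoded by the sign rule where it is missing.
draw_sequential_group <- function(joint, y_rows, method = c("truncated", "rejection"),
                                  max_tries = 100000L) {
  method <- match.arg(method)
  mu <- joint$mu_star; S <- joint$sigma_star
  p <- length(mu); d <- joint$d
  ng <- nrow(y_rows)
  z <- matrix(NA_real_, ng, p)
  yk <- y_rows
  for (j in seq_len(p)) {
    if (j == 1L) {
      cm <- rep(mu[1L], ng); v <- S[1, 1]
    } else {
      prev <- seq_len(j - 1L)
      w <- solve(S[prev, prev, drop = FALSE], S[prev, j])
      v <- S[j, j] - sum(S[j, prev] * w)
      cm <- mu[j] + drop(sweep(z[, prev, drop = FALSE], 2L, mu[prev]) %*% w)
    }
    v <- max(v, 1e-12)
    s <- sqrt(v)
    yv <- yk[, j]
    if (any(!is.na(yv))) {
      # guard against a vanishing acceptance region (would also stall the
      # literal rejection loop)
      pz <- stats::pnorm(-cm / s)
      prob <- ifelse(is.na(yv), 1, ifelse(yv == 1, pz, 1 - pz))
      if (any(prob < 1e-12)) stop("degenerate acceptance region", call. = FALSE)
    }
    if (method == "truncated") {
      z[, j] <- trunc_draw_vec(cm, s, yv, stats::runif(ng))
    } else {
      # literal accept/re-draw loop
      zj <- rep(NA_real_, ng)
      pending <- seq_len(ng)
      tries <- 0L
      while (length(pending)) {
        tries <- tries + 1L
        if (tries > max_tries) stop("degenerate acceptance region", call. = FALSE)
        prop <- cm[pending] + s * stats::rnorm(length(pending))
        ok <- is.na(yv[pending]) |
          (yv[pending] == 0 & prop > 0) | (yv[pending] == 1 & prop <= 0)
        zj[pending[ok]] <- prop[ok]
        pending <- pending[!ok]
      }
      z[, j] <- zj
    }
    dec <- as.numeric(z[, j] <= 0)
    yk[is.na(yv), j] <- dec[is.na(yv)]
  }
  list(z = z, y = yk)
}

#' Sequential reference-based latent draw for one patient
#'
#' Draws latent values visit by visit from the assumption-specific joint
#' latent distribution: each visit's value is drawn conditional on the
#' previously accepted latents, constrained to the region consistent with the
#' observed outcome (equivalently to the literal accept/re-draw loop, which is
#' available as `method = "rejection"`), and decoded to a binary value by the
#' sign rule where the outcome is missing.
#'
#' @param joint A `joint_distribution` on the latent scale (from
#'   [build_joint()] applied to latent-model draws).
#' @param y_row Binary outcomes for the patient (0/1/`NA`).
#' @param method `"truncated"` (inverse-CDF, default) or `"rejection"`.
#' @return List with `z` (latent vector) and `y` (completed binary row).
#' @export
sequential_reference_draw <- function(joint, y_row, method = c("truncated", "rejection")) {
  out <- draw_sequential_group(joint, matrix(y_row, nrow = 1L), method = method)
  list(z = drop(out$z), y = drop(out$y))
}

#' Reference-based multiple imputation via the latent-normal model (Method 2)
#'
#' Fits the latent multivariate normal model separately to each arm's observed
#' pre-deviation data, then for each of `K` retained parameter draws builds
#' each deviating patient's assumption-specific joint latent distribution,
#' draws latents sequentially (conditioning on observed outcomes) and decodes
#' post-deviation binary values by the sign rule. Completers are carried
#' through unchanged.
#'
#' @param data A validated [trial_data] object.
#' @param assumption One of `"MAR"`, `"J2R"`, `"CR"`, `"CIR"`, `"LMCF"`.
#' @param K Number of imputations (`>= 2`); one retained parameter draw is
#'   consumed per imputation.
#' @param config A [sampler_config()]; `n_draws` is forced to `K`.
#' @param draws Optional precomputed per-arm draws (list with elements
#'   `active`, `reference`, as from [gibbs_latent_fit()]); when supplied the
#'   model fit is skipped, e.g. to share one fit across assumptions.
#' @param engine MCMC engine passed to [gibbs_latent_fit()].
#' @param seed Optional master seed for the whole imputation run.
#' @return An `imputed_stack`.
#' @export
impute_latent <- function(data, assumption, K = 50L,
                          config = sampler_config(n_draws = K),
                          draws = NULL, engine = c("cpp", "r"), seed = NULL) {
  engine <- match.arg(engine)
  assumption <- match_assumption(assumption)
  assert_valid_trial(data)
  K <- as.integer(K)
  stopifnot(K >= 2L)
  config$n_draws <- K
  set_seed_if(seed)
  d <- deviation_times(data)
  p <- data$J_plus_1
  if (is.null(draws)) {
    draws <- list()
    for (a in c("active", "reference")) {
      cfg <- config
      cfg$seed <- if (is.null(seed)) NULL else substream_seed(seed, 1L, match(a, c("active", "reference")))
      draws[[a]] <- gibbs_latent_fit(data$y[data$arm == a, , drop = FALSE],
                                     cfg, engine = engine)
    }
  }
  completions <- vector("list", K)
  for (k in seq_len(K)) {
    if (!is.null(seed)) set.seed(substream_seed(seed, 2L, k))
    yk <- data$y
    pa <- draws$active[[k]]; pr <- draws$reference[[k]]
    for (a in c("active", "reference")) {
      for (dd in sort(unique(d[data$arm == a & d < p]))) {
        idx <- which(data$arm == a & d == dd)
        joint <- build_joint(assumption, a, pa$mu, pa$omega, pr$mu, pr$omega, dd)
        out <- draw_sequential_group(joint, data$y[idx, , drop = FALSE])
        yk[idx, ] <- out$y
      }
    }
    completions[[k]] <- yk
  }
  new_imputed_stack(data, completions, method = "latent", assumption = assumption,
                    K = K, seed = seed)
}
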