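#' MCMC sampler configuration
#'
#' Settings shared by the posterior samplers: the number of retained parameter
#' draws (one per imputation), the burn-in before the first retained draw and
#' the thinning interval between retained draws. The defaults (burn-in 500,
#' thinning 500) are deliberately conservative so that retained draws are
#' effectively independent.
#'
#' @param n_draws Number of retained draws `K >= 2`.
#' @param burn_in Iterations discarded before the first retained draw (`>= 0`).
#' @param thin Iterations between retained draws (`>= 1`).
#' @param seed Optional integer seed applied before sampling.
#' @return A `sampler_config` list.
#' @export
sampler_config <- function(n_draws = 50L, burn_in = 500L, thin = 500L, seed = NULL) {
  n_draws <- as.integer(n_draws); burn_in <- as.integer(burn_in); thin <- as.integer(thin)
  stopifnot(n_draws >= 2L, burn_in >= 0L, thin >= 1L)
  structure(list(n_draws = n_draws, burn_in = burn_in, thin = thin, seed = seed),
            class = "sampler_config")
}

# Group row indices by number of leading observed visits (monotone patterns).
monotone_groups <- function(y) {
  d <- rowSums(!is.na(y))
  split(seq_len(nrow(y)), d)
}

#' EM estimate of multivariate normal parameters with missing data
#'
#' Maximum-likelihood mean and covariance (divisor `n`) under MAR, computed by
#' expectation-maximization over the missingness patterns. With no missing
#' data this reduces to the closed-form sample moments. Used to initialize
#' the posterior sampler.
#'
#' @param y Numeric matrix with `NA` for missing entries.
#' @param tol Convergence tolerance on the change in log-likelihood.
#' @param max_iter Iteration cap.
#' @return List with `mu`, `sigma`, `loglik` (trace of observed-data
#'   log-likelihood), `converged`, `iterations`.
#' @export
em_mvn <- function(y, tol = 1e-8, max_iter = 1000L) {
  y <- as.matrix(y)
  n <- nrow(y); p <- ncol(y)
  if (n < p + 1L) stop("EM degenerate: add patients or reduce visits", call. = FALSE)
  obs_mask <- !is.na(y)
  patterns <- split(seq_len(n), apply(obs_mask, 1L, paste, collapse = ""))
  # start from complete-case-ish moments: observed means, diagonal covariance
  mu <- colMeans(y, na.rm = TRUE)
  v <- apply(y, 2L, stats::var, na.rm = TRUE)
  v[!is.finite(v) | v < 1e-8] <- 1e-8
  sigma <- diag(v, p)
  loglik <- -Inf; trace <- numeric(0); converged <- FALSE; it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    T1 <- numeric(p); T2 <- matrix(0, p, p); ll <- 0
    for (idx in patterns) {
      o <- which(obs_mask[idx[1L], ]); m <- setdiff(seq_len(p), o)
      yo <- y[idx, o, drop = FALSE]
      comp <- matrix(0, length(idx), p)
      comp[, o] <- yo
      if (length(m)) {
        if (length(o)) {
          B <- solve(sigma[o, o, drop = FALSE], sigma[o, m, drop = FALSE])
          comp[, m] <- rep(mu[m], each = length(idx)) +
            sweep(yo, 2L, mu[o]) %*% B
          Cm <- sigma[m, m, drop = FALSE] -
            crossprod(sigma[o, m, drop = FALSE], B)
        } else {
          comp[, m] <- rep(mu[m], each = length(idx))
          Cm <- sigma[m, m, drop = FALSE]
        }
        T2[m, m] <- T2[m, m] + length(idx) * sym(Cm)
      }
      if (length(o)) {
        ll <- ll + mvn_loglik_block(yo, mu[o], sigma[o, o, drop = FALSE])
      }
      T1 <- T1 + colSums(comp)
      T2 <- T2 + crossprod(comp)
    }
    mu <- T1 / n
    sigma <- sym(T2 / n - tcrossprod(mu))
    if (any(diag(sigma) < 1e-12) || is.null(chol_or_null(sigma))) {
      stop("EM degenerate: add patients or reduce visits", call. = FALSE)
    }
    trace <- c(trace, ll)
    if (is.finite(loglik) && ll - loglik < tol * (abs(loglik) + 1)) {
      converged <- TRUE
      loglik <- ll
      break
    }
    loglik <- ll
  }
  list(mu = unname(mu), sigma = unname(sigma), loglik = trace,
       converged = converged, iterations = it)
}

# One scan of the data-augmentation chain, R reference engine; state is a
# list(mu, sigma). RNG call order matches cpp_da_mvn exactly.
da_mvn_scan_r <- function(y, groups, state) {
  p <- ncol(y); n <- nrow(y)
  mu <- state$mu; sigma <- state$sigma
  # I-step: draw missing suffixes from their conditional given the observed
  # prefix at the current parameters (groups keyed by deviation time, ascending)
  for (dd in names(groups)) {
    d <- as.integer(dd)
    if (d >= p) next
    idx <- groups[[dd]]
    o <- seq_len(d); m <- seq.int(d + 1L, p)
    B <- solve(sigma[o, o, drop = FALSE], sigma[o, m, drop = FALSE])
    cm <- rep(mu[m], each = length(idx)) +
      sweep(y[idx, o, drop = FALSE], 2L, mu[o]) %*% B
    Cm <- sym(sigma[m, m, drop = FALSE] - crossprod(sigma[o, m, drop = FALSE], B))
    U <- chol(Cm)
    eps <- matrix(stats::rnorm(length(idx) * length(m)), length(idx), length(m),
                  byrow = TRUE)
    y[idx, m] <- cm + eps %*% U
  }
  # P-step: complete-data conjugate draw under the Jeffreys prior
  ybar <- colMeans(y)
  S <- crossprod(sweep(y, 2L, ybar))
  sigma_new <- riwish_bartlett(n - 1L, S)
  mu_new <- ybar + drop(t(chol(sigma_new)) %*% stats::rnorm(p)) / sqrt(n)
  list(mu = mu_new, sigma = sigma_new, y = y)
}

da_mvn_r <- function(y, burn_in, thin, n_draws, init) {
  groups <- monotone_groups(y)
  groups <- groups[order(as.integer(names(groups)))]
  state <- list(mu = init$mu, sigma = init$sigma)
  total <- burn_in + (n_draws - 1L) * thin + 1L
  draws <- vector("list", n_draws); got <- 0L
  for (t in seq_len(total)) {
    st <- da_mvn_scan_r(y, groups, state)
    state <- list(mu = st$mu, sigma = st$sigma)
    y <- st$y
    if (t > burn_in && (t - burn_in - 1L) %% thin == 0L) {
      got <- got + 1L
      draws[[got]] <- list(mu = state$mu, sigma = state$sigma)
    }
  }
  draws
}

#' Posterior draws of multivariate normal parameters for one arm
#'
#' Treats the (binary) outcome matrix as continuous and draws `(mu, sigma)`
#' from the Bayesian posterior under an improper flat prior for the mean and
#' the Jeffreys prior \eqn{|\Sigma|^{-(p+1)/2}} for the covariance. With fully
#' observed data the draws come directly from the conjugate posterior
#' (covariance inverse-Wishart with `n - 1` degrees of freedom and the centred
#' sum-of-squares scale; mean normal around the sample mean with covariance
#' `sigma / n`). With monotone missing data, draws are produced by an
#' I-step/P-step data-augmentation chain whose stationary distribution is that
#' posterior marginalized over the missing values, initialized from [em_mvn()]
#' and retained per the burn-in/thinning schedule in `config`.
#'
#' @param y Numeric matrix (one arm), `NA` for missing entries.
#' @param config A [sampler_config()].
#' @param engine `"cpp"` (default) or `"r"` (reference implementation; both
#'   consume the RNG stream identically, so seeded results agree).
#' @return List of `n_draws` draws, each a list with `mu` and `sigma`.
#' @export
draw_mvn_posterior <- function(y, config = sampler_config(), engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  y <- as.matrix(y)
  storage.mode(y) <- "double"
  n <- nrow(y); p <- ncol(y)
  if (n < p + 1L) stop("posterior improper: fewer patients than visits + 1", call. = FALSE)
  set_seed_if(config$seed)
  const_col <- apply(y, 2L, function(col) stats::var(col[!is.na(col)]) < 1e-12)
  if (any(const_col)) {
    warning("degenerate binary column(s) ", paste(which(const_col), collapse = ", "),
            ": observed values constant; ridging covariance", call. = FALSE)
  }
  if (!anyNA(y)) {
    ybar <- colMeans(y)
    S <- crossprod(sweep(y, 2L, ybar))
    if (any(const_col)) S <- S + diag(1e-8, p)
    return(lapply(seq_len(config$n_draws), function(k) {
      sigma <- riwish_bartlett(n - 1L, S)
      mu <- ybar + drop(t(chol(sigma)) %*% stats::rnorm(p)) / sqrt(n)
      list(mu = mu, sigma = sigma)
    }))
  }
  init <- em_mvn(y)
  if (any(const_col)) init$sigma <- init$sigma + diag(1e-8, p)
  if (engine == "cpp") {
    d <- as.integer(rowSums(!is.na(y)))
    out <- cpp_da_mvn(y, d, config$burn_in, config$thin, config$n_draws,
                      init$mu, init$sigma)
    lapply(seq_len(config$n_draws), function(k) {
      list(mu = drop(out$mu[k, ]), sigma = out$sigma[[k]])
    })
  } else {
    da_mvn_r(y, config$burn_in, config$thin, config$n_draws, init)
  }
}
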