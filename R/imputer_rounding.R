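# Method 1: multivariate normal imputation of the binary outcomes treated as
# continuous, followed by adaptive rounding back to 0/1.

#' Adaptive rounding threshold
#'
#' Cut-off for recoding continuous imputations to binary, based on the normal
#' approximation to the binomial at the variable's current mean:
#' \deqn{c = \bar Y - \Phi^{-1}(\bar Y)\sqrt{\bar Y (1 - \bar Y)}.}
#' Satisfies the symmetry `c(p) + c(1 - p) = 1`. For the degenerate means 0
#' and 1 the threshold is the sentinel `+Inf` / `-Inf`, so that the recode
#' rule maps every imputed value to the single observed category.
#'
#' @param ybar Proportion(s) in `[0, 1]`: the mean of the observed binary and
#'   imputed continuous values for one visit in one imputed dataset.
#' @return Threshold(s) on the continuous scale.
#' @examples
#' adaptive_threshold(0.5)          # 0.5
#' adaptive_threshold(0.8413447)    # ~0.476
#' @export
adaptive_threshold <- function(ybar) {
  if (any(!is.finite(ybar)) || any(ybar < 0) || any(ybar > 1)) {
    stop("ybar must lie in [0, 1]", call. = FALSE)
  }
  out <- ybar - stats::qnorm(ybar) * sqrt(ybar * (1 - ybar))
  out[ybar == 0] <- Inf     # degenerate: everything recodes to 0
  out[ybar == 1] <- -Inf    # degenerate: everything recodes to 1
  out
}

#' Recode continuous values to binary by per-visit thresholds
#'
#' Values less than or equal to the visit's threshold become 0; values above
#' it become 1.
#'
#' @param y_cont Numeric matrix (patients by visits).
#' @param thresholds Numeric vector with one threshold per visit.
#' @return Binary matrix of the same shape.
#' @export
recode_binary <- function(y_cont, thresholds) {
  y_cont <- as.matrix(y_cont)
  stopifnot(length(thresholds) == ncol(y_cont))
  out <- (y_cont > rep(thresholds, each = nrow(y_cont))) * 1
  dimnames(out) <- dimnames(y_cont)
  out
}

#' Reference-based multiple imputation via MVN and adaptive rounding (Method 1)
#'
#' Treats the binary outcomes as continuous, fits a multivariate normal model
#' per arm by [draw_mvn_posterior()], builds each deviating patient's
#' assumption-specific joint distribution, samples post-deviation values from
#' the conditional given the observed prefix, and finally recodes the
#' continuous imputations to 0/1 with [adaptive_threshold()] computed per
#' visit and per imputation from the observed binary and imputed continuous
#' values pooled across both treatment arms.
#'
#' @inheritParams impute_latent
#' @param draws Optional precomputed per-arm draws (list with elements
#'   `active`, `reference`, as from [draw_mvn_posterior()]).
#' @param threshold_arms `"pooled"` (default; thresholds from both arms
#'   together) or `"by_arm"`.
#' @return An `imputed_stack`.
#' @export
impute_mvn_rounding <- function(data, assumption, K = 50L,
                                config = sampler_config(n_draws = K),
                                draws = NULL, engine = c("cpp", "r"),
                                threshold_arms = c("pooled", "by_arm"),
                                seed = NULL) {
  engine <- match.arg(engine)
  threshold_arms <- match.arg(threshold_arms)
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
      draws[[a]] <- draw_mvn_posterior(data$y[data$arm == a, , drop = FALSE],
                                       cfg, engine = engine)
    }
  }
  miss <- is.na(data$y)
  completions <- vector("list", K)
  degenerate_seen <- FALSE
  for (k in seq_len(K)) {
    if (!is.null(seed)) set.seed(substream_seed(seed, 2L, k))
    ycont <- data$y
    pa <- draws$active[[k]]; pr <- draws$reference[[k]]
    for (a in c("active", "reference")) {
      for (dd in sort(unique(d[data$arm == a & d < p]))) {
        idx <- which(data$arm == a & d == dd)
        joint <- build_joint(assumption, a, pa$mu, pa$sigma, pr$mu, pr$sigma, dd)
        pre <- seq_len(dd); post <- seq.int(dd + 1L, p)
        S11 <- joint$sigma_star[pre, pre, drop = FALSE]
        S12 <- joint$sigma_star[pre, post, drop = FALSE]
        S22 <- joint$sigma_star[post, post, drop = FALSE]
        B <- solve(S11, S12)
        cm <- rep(joint$mu_star[post], each = length(idx)) +
          sweep(data$y[idx, pre, drop = FALSE], 2L, joint$mu_star[pre]) %*% B
        Cc <- sym(S22 - crossprod(S12, B))
        U <- chol(Cc)
        eps <- matrix(stats::rnorm(length(idx) * length(post)),
                      length(idx), length(post))
        ycont[idx, post] <- cm + eps %*% U
      }
    }
    # adaptive rounding: thresholds from the completed continuous data
    yk <- data$y
    if (threshold_arms == "pooled") {
      ybar <- pmin(pmax(colMeans(ycont), 0), 1)
      cj <- adaptive_threshold(ybar)
      if (any(ybar == 0 | ybar == 1)) degenerate_seen <- TRUE
      rec <- recode_binary(ycont, cj)
    } else {
      rec <- ycont
      for (a in c("active", "reference")) {
        rows <- data$arm == a
        ybar <- pmin(pmax(colMeans(ycont[rows, , drop = FALSE]), 0), 1)
        cj <- adaptive_threshold(ybar)
        if (any(ybar == 0 | ybar == 1)) degenerate_seen <- TRUE
        rec[rows, ] <- recode_binary(ycont[rows, , drop = FALSE], cj)
      }
    }
    yk[miss] <- rec[miss]
    completions[[k]] <- yk
  }
  if (degenerate_seen) {
    warning("degenerate visit mean (0 or 1); imputed values recoded to the constant",
            call. = FALSE)
  }
  new_imputed_stack(data, completions, method = "mvn_rounding",
                    assumption = assumption, K = K, seed = seed)
}
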