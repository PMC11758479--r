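#' Jump-to-reference covariance construction
#'
#' Combines the active-arm and reference-arm covariance matrices at a
#' deviation time `d` into the covariance used by the jump-to-reference,
#' copy-reference and copy-increments-in-reference joint distributions.
#' Partitioning both matrices into pre-deviation (visits `1..d`, block 1) and
#' post-deviation (visits `d+1..J+1`, block 2) parts, the result is the unique
#' symmetric matrix satisfying
#' \deqn{\Sigma_{11} = A_{11}, \quad
#'       \Sigma_{21}\Sigma_{11}^{-1} = R_{21}R_{11}^{-1}, \quad
#'       \Sigma_{22} - \Sigma_{21}\Sigma_{11}^{-1}\Sigma_{12}
#'         = R_{22} - R_{21}R_{11}^{-1}R_{12},}
#' i.e. pre-deviation variances from the active arm, with the reference arm's
#' regression of post on pre and the reference arm's conditional covariance.
#' Positive definiteness of both inputs implies positive definiteness of the
#' result.
#'
#' @param sigma_a,sigma_r Symmetric positive-definite covariance matrices for
#'   the active and reference arm (same dimension).
#' @param d Deviation time, `1 <= d <= J` (at least one post-deviation visit).
#' @return The combined covariance matrix.
#' @examples
#' sigma_j2r(matrix(c(2, .4, .4, 1), 2), matrix(c(1, .6, .6, 1), 2), d = 1)
#' @export
sigma_j2r <- function(sigma_a, sigma_r, d) {
  sigma_a <- as.matrix(sigma_a); sigma_r <- as.matrix(sigma_r)
  p <- ncol(sigma_a)
  stopifnot(ncol(sigma_r) == p, d >= 1, d <= p - 1)
  stopifnot_spd(sigma_a); stopifnot_spd(sigma_r)
  pre <- seq_len(d); post <- seq.int(d + 1L, p)
  A11 <- sigma_a[pre, pre, drop = FALSE]
  R11 <- sigma_r[pre, pre, drop = FALSE]
  R12 <- sigma_r[pre, post, drop = FALSE]
  R22 <- sigma_r[post, post, drop = FALSE]
  W <- t(solve(R11, R12))                 # R21 R11^{-1}
  S21 <- W %*% A11
  S22 <- sym(R22 - W %*% R12 + S21 %*% solve(A11, t(S21)))
  out <- matrix(0, p, p)
  out[pre, pre] <- A11
  out[post, pre] <- S21
  out[pre, post] <- t(S21)
  out[post, post] <- S22
  sym(out)
}

#' Assumption-specific joint distribution for a deviating patient
#'
#' Builds the patient-level multivariate normal over all `J+1` visits implied
#' by the chosen post-deviation assumption, from per-arm mean vectors and
#' covariance matrices (posterior draws, or true parameters in simulation).
#' With deviation at `d` and writing `t` for the patient's own arm:
#' \describe{
#'   \item{MAR}{own-arm mean \eqn{\mu_t} and covariance \eqn{\Sigma_t} throughout.}
#'   \item{J2R}{mean \eqn{(\mu_{a,1..d}, \mu_{r,d+1..J+1})}, covariance [sigma_j2r()].}
#'   \item{CR}{mean \eqn{\mu_r} at every visit, covariance [sigma_j2r()].}
#'   \item{CIR}{own-arm mean to `d`, thereafter the reference arm's increments
#'     carried on from \eqn{\mu_{a,d}}; covariance [sigma_j2r()].}
#'   \item{LMCF}{own-arm mean to `d`, frozen at \eqn{\mu_{t,d}} thereafter;
#'     own-arm covariance.}
#' }
#' For a reference-arm patient, J2R, CR and CIR all reduce to MAR. A completer
#' (`d = J+1`) has an empty post-deviation block and the own-arm MAR joint is
#' returned, so imputers can loop uniformly over patients.
#'
#' @param assumption One of `"MAR"`, `"J2R"`, `"CR"`, `"CIR"`, `"LMCF"`.
#' @param arm `"active"` or `"reference"`: the patient's randomized arm.
#' @param mu_a,mu_r Mean vectors for the active and reference arm.
#' @param sigma_a,sigma_r Covariance matrices for the two arms.
#' @param d Deviation time in `1..J+1`.
#' @return A `joint_distribution`: list with `mu_star`, `sigma_star`, `d`.
#' @examples
#' build_joint("CIR", "active", mu_a = c(1, 2, 3), sigma_a = diag(3),
#'             mu_r = c(0, 1, 4), sigma_r = diag(3), d = 2)
#' @export
build_joint <- function(assumption, arm, mu_a, sigma_a, mu_r, sigma_r, d) {
  assumption <- match_assumption(assumption)
  arm <- match.arg(arm, c("active", "reference"))
  p <- length(mu_a)
  stopifnot(length(mu_r) == p, d >= 1, d <= p)
  own_mu <- if (arm == "active") mu_a else mu_r
  own_sigma <- if (arm == "active") sigma_a else sigma_r
  # Reference-arm patients keep their own (reference) distribution under the
  # reference-based options; completers have nothing to borrow.
  if (assumption %in% c("J2R", "CR", "CIR") && (arm == "reference" || d == p)) {
    assumption <- "MAR"
  }
  post <- if (d < p) seq.int(d + 1L, p) else integer()
  res <- switch(assumption,
    MAR = list(mu = own_mu, sigma = own_sigma),
    LMCF = list(mu = c(own_mu[seq_len(d)], rep(own_mu[d], p - d)),
                sigma = own_sigma),
    J2R = list(mu = c(mu_a[seq_len(d)], mu_r[post]),
               sigma = sigma_j2r(sigma_a, sigma_r, d)),
    CR = list(mu = mu_r,
              sigma = sigma_j2r(sigma_a, sigma_r, d)),
    # CIR written as reference mean plus a constant offset so that equal
    # baseline means make CIR coincide exactly (bitwise) with J2R/CR.
    CIR = list(mu = c(mu_a[seq_len(d)], mu_r[post] + (mu_a[d] - mu_r[d])),
               sigma = sigma_j2r(sigma_a, sigma_r, d)))
  structure(list(mu_star = unname(res$mu), sigma_star = unname(sym(as.matrix(res$sigma))),
                 d = as.integer(d)),
            class = "joint_distribution")
}

#' Conditional distribution of post-deviation values given the observed prefix
#'
#' Standard multivariate normal conditioning of the post-deviation block
#' (visits `d+1..J+1`) on observed values at visits `1..d`, using the
#' Schur-complement form with factorization-based solves. For a completer
#' (`d = J+1`) an empty conditional is returned.
#'
#' @param joint A `joint_distribution` from [build_joint()].
#' @param observed Numeric vector of length `d`: values at visits `1..d`.
#' @return A `conditional_normal`: list with `mean` (length `J+1-d`) and
#'   `cov` (`(J+1-d)` square).
#' @examples
#' j <- build_joint("MAR", "active", c(0, 0), matrix(c(1, .6, .6, 1), 2),
#'                  c(0, 0), diag(2), d = 1)
#' condition_on_observed(j, observed = 1)  # N(0.6, 0.64)
#' @export
condition_on_observed <- function(joint, observed) {
  stopifnot(inherits(joint, "joint_distribution"))
  p <- length(joint$mu_star); d <- joint$d
  stopifnot(length(observed) == d)
  if (d == p) {
    return(structure(list(mean = numeric(0), cov = matrix(0, 0, 0)),
                     class = "conditional_normal"))
  }
  pre <- seq_len(d); post <- seq.int(d + 1L, p)
  S11 <- joint$sigma_star[pre, pre, drop = FALSE]
  S12 <- joint$sigma_star[pre, post, drop = FALSE]
  S22 <- joint$sigma_star[post, post, drop = FALSE]
  B <- solve(S11, S12)                     # S11^{-1} S12
  mean <- joint$mu_star[post] + drop(crossprod(B, observed - joint$mu_star[pre]))
  cov <- sym(S22 - crossprod(S12, B))
  structure(list(mean = mean, cov = cov), class = "conditional_normal")
}
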