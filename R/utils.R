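# Internal helpers shared across modules.

ASSUMPTIONS <- c("MAR", "J2R", "CR", "CIR", "LMCF")

match_assumption <- function(assumption) {
  a <- toupper(as.character(assumption)[1L])
  if (!a %in% ASSUMPTIONS) {
    stop("unknown assumption '", assumption, "'; must be one of ",
         paste(ASSUMPTIONS, collapse = ", "), call. = FALSE)
  }
  a
}

`%||%` <- function(a, b) if (is.null(a)) b else a

sym <- function(m) (m + t(m)) / 2

#' Derive a reproducible substream seed
#'
#' All randomness in the package flows from one master seed; independent
#' components (replicates, arm fits, imputation draws) consume seeds derived
#' deterministically from the master seed and an integer key path, so results
#' do not depend on evaluation order. The mixing is a fixed-modulus linear
#' congruence, exact in double precision, with output in `[1, 2^31 - 2]`.
#'
#' @param master Integer master seed.
#' @param ... Further integer keys identifying the substream.
#' @return A single integer usable with [set.seed()].
#' @export
substream_seed <- function(master, ...) {
  keys <- c(master, ...)
  h <- 104729
  for (k in keys) {
    h <- (h * 69069 + abs(as.double(k)) + 1) %% 2147483629
  }
  as.integer(h %% 2147483645L + 1)
}

set_seed_if <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

# Cholesky that fails softly: returns NULL for a non-PD matrix.
chol_or_null <- function(m) {
  tryCatch(chol(m), error = function(e) NULL)
}

stopifnot_spd <- function(m, what = "covariance") {
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8)) || is.null(chol_or_null(sym(m)))) {
    stop(what, " not positive definite", call. = FALSE)
  }
  invisible(TRUE)
}

# Draw n rows from N(mu, sigma); chol-based, no external dependency.
rmvn <- function(n, mu, sigma) {
  p <- length(mu)
  u <- chol(sym(sigma))
  matrix(stats::rnorm(n * p), n, p) %*% u + rep(mu, each = n)
}

# Log-density of observed sub-vectors under N(mu, sigma); y is a matrix whose
# columns idx are all observed.
mvn_loglik_block <- function(y, mu, sigma) {
  u <- chol(sym(sigma))
  p <- length(mu)
  centred <- sweep(y, 2L, mu)
  q <- backsolve(u, t(centred), transpose = TRUE)
  -0.5 * nrow(y) * (p * log(2 * pi) + 2 * sum(log(diag(u)))) - 0.5 * sum(q^2)
}

# Inverse-Wishart draw via the Bartlett decomposition. The explicit scalar
# draw order (diagonal chi-square then sub-diagonal normals, column-major)
# is part of the contract: the C++ sampler consumes the RNG stream in exactly
# the same order, so seeded runs agree across engines.
riwish_bartlett <- function(df, S) {
  p <- ncol(S)
  if (df < p) stop("inverse-Wishart degrees of freedom below dimension", call. = FALSE)
  V <- chol2inv(chol(sym(S)))
  Lv <- t(chol(sym(V)))
  A <- matrix(0, p, p)
  for (j in seq_len(p)) {
    A[j, j] <- sqrt(stats::rchisq(1, df - j + 1))
    if (j < p) {
      for (i in seq.int(j + 1L, p)) A[i, j] <- stats::rnorm(1)
    }
  }
  LA <- Lv %*% A
  W <- LA %*% t(LA)
  sym(chol2inv(chol(sym(W))))
}
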