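# Substantive analysis and Rubin's rules combination.

#' Log odds ratio of the final-visit outcome on treatment
#'
#' The substantive analysis model: a logistic regression of the binary
#' outcome at the last visit on treatment arm. With treatment as the sole
#' covariate the maximum-likelihood estimate is the closed-form 2x2-table log
#' odds ratio (active vs reference) with the Woolf standard error
#' `sqrt(1/a + 1/b + 1/c + 1/d)`, which is what this returns.
#'
#' @param data A [trial_data] object (or completed matrix via `y`/`arm`
#'   below) whose last visit is fully observed, or a binary outcome vector.
#' @param arm If `data` is a vector, the matching arm factor/character vector
#'   (`"active"`/`"reference"`).
#' @return A `logor_fit`: list with `estimate` (log OR), `se`, `variance`,
#'   and the 2x2 `cells` (active 1/0, reference 1/0).
#' @examples
#' fit_logistic(c(rep(1, 39), rep(0, 31), rep(1, 25), rep(0, 36)),
#'              rep(c("active", "reference"), c(70, 61)))
#' @export
fit_logistic <- function(data, arm = NULL) {
  if (inherits(data, "trial_data")) {
    y <- data$y[, data$J_plus_1]
    arm <- data$arm
  } else if (is.matrix(data)) {
    stopifnot(!is.null(arm))
    y <- data[, ncol(data)]
  } else {
    stopifnot(!is.null(arm))
    y <- data
  }
  if (anyNA(y)) stop("final-visit outcome must be complete", call. = FALSE)
  arm <- as.character(arm)
  a <- sum(y == 1 & arm == "active")
  b <- sum(y == 0 & arm == "active")
  cc <- sum(y == 1 & arm == "reference")
  dd <- sum(y == 0 & arm == "reference")
  if (min(a, b, cc, dd) == 0L) {
    stop("separation: log-OR undefined (zero cell in 2x2 table)", call. = FALSE)
  }
  est <- log(a) - log(b) - log(cc) + log(dd)
  se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / dd)
  structure(list(estimate = est, se = se, variance = se^2,
                 cells = c(active_1 = a, active_0 = b,
                           reference_1 = cc, reference_0 = dd)),
            class = "logor_fit")
}

#' @export
print.logor_fit <- function(x, ...) {
  cat(sprintf("log-OR %.4f (SE %.4f), OR %.4f\n", x$estimate, x$se,
              exp(x$estimate)))
  invisible(x)
}

#' Combine per-imputation estimates by Rubin's rules
#'
#' Pools `K` estimates and their variances: `qbar` is the mean estimate, `w`
#' the within-imputation variance (mean of the variances), `b` the
#' between-imputation variance (sample variance of the estimates), and the
#' total variance `t_var = w + (1 + 1/K) b`. Degrees of freedom use the
#' Barnard-Rubin small-sample adjustment by default (with complete-data
#' degrees of freedom `n_complete - 2`), or the classic large-sample formula
#' `(K-1)(1 + w / ((1+1/K) b))^2`. The confidence interval and p-value use
#' the t reference distribution.
#'
#' @param estimates Numeric vector of K point estimates (log odds ratios).
#' @param variances Numeric vector of K squared standard errors.
#' @param n_complete Number of analysed patients, for the complete-data
#'   degrees of freedom `n_complete - 2`; `NULL` implies the classic formula.
#' @param df_method `"barnard-rubin"` (default) or `"classic"`.
#' @param conf_level Confidence level, default 0.95.
#' @return A `pooled_result`: list with `qbar`, `w`, `b`, `t_var`, `se`,
#'   `df`, `ci_low`, `ci_high`, `p`, `K`, `mc_error` (Monte-Carlo standard
#'   error of `qbar` over imputations).
#' @export
rubin_pool <- function(estimates, variances, n_complete = NULL,
                       df_method = c("barnard-rubin", "classic"),
                       conf_level = 0.95) {
  df_method <- match.arg(df_method)
  K <- length(estimates)
  if (K < 2L) stop("Rubin's rules require K >= 2 imputations", call. = FALSE)
  stopifnot(length(variances) == K, all(variances > 0))
  qbar <- mean(estimates)
  w <- mean(variances)
  b <- stats::var(estimates)
  t_var <- w + (1 + 1 / K) * b
  nu_com <- if (is.null(n_complete)) Inf else n_complete - 2
  if (b == 0) {
    # no between-imputation variation: inference at the complete-data df
    df <- nu_com
  } else {
    lambda <- (1 + 1 / K) * b / t_var
    nu_old <- (K - 1) / lambda^2
    df <- if (df_method == "classic" || !is.finite(nu_com)) nu_old else {
      nu_obs <- (nu_com + 1) / (nu_com + 3) * nu_com * (1 - lambda)
      1 / (1 / nu_old + 1 / nu_obs)
    }
  }
  se <- sqrt(t_var)
  alpha <- 1 - conf_level
  tq <- if (is.finite(df)) stats::qt(1 - alpha / 2, df) else stats::qnorm(1 - alpha / 2)
  p <- if (is.finite(df)) 2 * stats::pt(-abs(qbar) / se, df) else
    2 * stats::pnorm(-abs(qbar) / se)
  structure(list(qbar = qbar, w = w, b = b, t_var = t_var, se = se, df = df,
                 ci_low = qbar - tq * se, ci_high = qbar + tq * se, p = p,
                 K = K, mc_error = stats::sd(estimates) / sqrt(K),
                 conf_level = conf_level, df_method = df_method),
            class = "pooled_result")
}

#' @export
print.pooled_result <- function(x, ...) {
  cat(sprintf("Pooled log-OR %.4f (SE %.4f), OR %.3f [%.3f, %.3f], df %.1f, p %.4g (K = %d)\n",
              x$qbar, x$se, exp(x$qbar), exp(x$ci_low), exp(x$ci_high),
              x$df, x$p, x$K))
  cat(sprintf("within %.5f | between %.5f | total %.5f | mc error %.4f\n",
              x$w, x$b, x$t_var, x$mc_error))
  invisible(x)
}

#' Fit and pool across an imputed stack
#'
#' Applies [fit_logistic()] to each completed dataset and combines the K
#' log odds ratios with [rubin_pool()].
#'
#' @param stack An `imputed_stack`.
#' @param on_separation `"error"` (default) or `"drop"`: what to do when a
#'   completed dataset has a zero cell. Dropped fits are counted in the
#'   result's `n_dropped` attribute; at least 2 fits must remain.
#' @inheritParams rubin_pool
#' @return A `pooled_result`.
#' @export
pool_imputations <- function(stack, df_method = c("barnard-rubin", "classic"),
                             on_separation = c("error", "drop"),
                             conf_level = 0.95) {
  stopifnot(inherits(stack, "imputed_stack"))
  on_separation <- match.arg(on_separation)
  arm <- stack$data$arm
  fits <- lapply(stack$completions, function(yk) {
    if (on_separation == "drop") {
      tryCatch(fit_logistic(yk, arm), error = function(e) NULL)
    } else {
      fit_logistic(yk, arm)
    }
  })
  dropped <- sum(vapply(fits, is.null, TRUE))
  fits <- fits[!vapply(fits, is.null, TRUE)]
  if (length(fits) < 2L) stop("separation left fewer than 2 usable imputations",
                              call. = FALSE)
  out <- rubin_pool(vapply(fits, `[[`, 0, "estimate"),
                    vapply(fits, `[[`, 0, "variance"),
                    n_complete = nrow(stack$data$y),
                    df_method = df_method, conf_level = conf_level)
  attr(out, "n_dropped") <- dropped
  out
}
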