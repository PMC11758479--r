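# Simulation laboratory: multivariate probit data generation, MAR deviation,
# reference-based regeneration of post-deviation truth, large-sample true
# values, and performance measures including information anchoring.

#' Deviation mechanism for one visit
#'
#' Logistic model for remaining on treatment at one visit: the probability of
#' being observed on-treatment is `plogis(sum(intercepts) + slope * y1)`,
#' where `y1` is the patient's baseline outcome. Deviation at a visit implies
#' deviation at all later visits.
#'
#' @param visit Visit index (`2..J+1`) at which deviation can first show.
#' @param intercepts Numeric vector of intercept terms (summed).
#' @param slope Coefficient on the baseline outcome.
#' @return A `deviation_mechanism` list.
#' @export
deviation_mechanism <- function(visit, intercepts, slope) {
  stopifnot(visit >= 2L)
  structure(list(visit = as.integer(visit),
                 intercepts = as.numeric(intercepts),
                 slope = as.numeric(slope)),
            class = "deviation_mechanism")
}

#' Simulation scenario
#'
#' Bundles the multivariate probit generating model (latent means per arm and
#' a common latent correlation matrix; `Y = 1` iff the latent value is at or
#' below zero), the per-arm deviation mechanisms and the post-deviation truth
#' assumption.
#'
#' @param mu_r,mu_a Latent mean vectors (length `J+1`).
#' @param sigma Latent correlation matrix, unit diagonal.
#' @param n_per_arm Patients per arm.
#' @param dev_active List of [deviation_mechanism()]s for the active arm
#'   (empty list for no deviation).
#' @param dev_reference List of [deviation_mechanism()]s for the reference
#'   arm, or `NULL` for none.
#' @param truth Assumption governing regeneration of post-deviation truth.
#' @param label Optional scenario name.
#' @return A `scenario` object.
#' @export
scenario <- function(mu_r, mu_a, sigma, n_per_arm = 250L,
                     dev_active = list(), dev_reference = NULL,
                     truth = "CR", label = NULL) {
  mu_r <- as.numeric(mu_r); mu_a <- as.numeric(mu_a)
  sigma <- as.matrix(sigma)
  stopifnot(length(mu_r) == length(mu_a), ncol(sigma) == length(mu_r),
            isTRUE(all.equal(diag(sigma), rep(1, ncol(sigma)))))
  stopifnot_spd(sigma)
  if (inherits(dev_active, "deviation_mechanism")) dev_active <- list(dev_active)
  if (inherits(dev_reference, "deviation_mechanism")) dev_reference <- list(dev_reference)
  structure(list(mu_r = mu_r, mu_a = mu_a, sigma = sigma,
                 n_per_arm = as.integer(n_per_arm),
                 dev_active = dev_active, dev_reference = dev_reference,
                 truth = vapply(truth, match_assumption, "", USE.NAMES = FALSE),
                 label = label %||% "scenario"),
            class = "scenario")
}

# Table of latent means for the bundled trial-inspired settings: five outcome
# prevalence rows for a baseline + single follow-up design and for a design
# with three post-baseline measurement times.
PRESET_SINGLE <- list(
  mu_r = list(c(1.57, 0.26), c(1.57, 0.53), c(1.57, 0.83), c(1.57, 1.30),
              c(1.57, 1.56)),
  mu_a = list(c(1.57, -0.13), c(1.57, 0.16), c(1.57, 0.43), c(1.57, 0.85),
              c(1.57, 1.30)))
PRESET_THREE <- list(
  mu_r = list(c(1.57, 0.54, 0.26), c(1.57, 1.05, 0.53), c(1.57, 1.2, 0.83),
              c(1.57, 1.44, 1.30), c(1.57, 1.565, 1.56)),
  mu_a = list(c(1.33, 0.41, -0.13), c(1.33, 0.75, 0.16), c(1.33, 0.88, 0.43),
              c(1.33, 1.11, 0.85), c(1.33, 1.315, 1.30)))

# deviation intercept add-ons giving the three active-arm missingness levels
DEV_TERM_SINGLE <- c("30" = 0.032, "15" = 0.932, "5" = 2.132)
DEV_TERM_THREE_V2 <- c("15" = 1.729, "7" = 2.629, "2" = 3.829)

#' Bundled trial-inspired scenarios
#'
#' Constructs one of the study scenarios: an outcome-prevalence row (1 = most
#' common, 40% reference vs 55% active at the final visit; 5 = rarest, 6% vs
#' 10%), a single- or three-follow-up design, and an active-arm missingness
#' level (nominal percent at the final visit). Deviation follows the logistic
#' MAR mechanisms of the study design; `both_arms = TRUE` adds the
#' reference-arm mechanisms.
#'
#' @param row Prevalence row 1-5.
#' @param followups 1 (baseline + single follow-up) or 3.
#' @param missing `"30"`, `"15"` or `"5"`: nominal active-arm deviation level.
#' @param both_arms Also impose deviation in the reference arm.
#' @param truth Post-deviation truth assumption.
#' @param n_per_arm Patients per arm (default 250).
#' @return A `scenario` object.
#' @export
scenario_preset <- function(row = 1L, followups = 1L, missing = c("30", "15", "5"),
                            both_arms = FALSE, truth = "CR", n_per_arm = 250L) {
  missing <- match.arg(as.character(missing), c("30", "15", "5"))
  stopifnot(row %in% 1:5, followups %in% c(1L, 3L))
  if (followups == 1L) {
    mu_r <- PRESET_SINGLE$mu_r[[row]]; mu_a <- PRESET_SINGLE$mu_a[[row]]
    sigma <- matrix(c(1, 0.6, 0.6, 1), 2)
    dev_a <- list(deviation_mechanism(2L, c(0.367, DEV_TERM_SINGLE[[missing]]), 1.167))
    dev_r <- if (both_arms)
      list(deviation_mechanism(2L, c(0, DEV_TERM_SINGLE[[missing]]), 1.167))
  } else {
    mu_r <- PRESET_THREE$mu_r[[row]]; mu_a <- PRESET_THREE$mu_a[[row]]
    sigma <- matrix(c(1, 0.4, 0.5, 0.4, 1, 0.6, 0.5, 0.6, 1), 3)
    v2 <- switch(missing, "30" = "15", "15" = "7", "5" = "2")
    dev_a <- list(deviation_mechanism(2L, c(-0.027, DEV_TERM_THREE_V2[[v2]]), 0.005),
                  deviation_mechanism(3L, c(0.367, DEV_TERM_SINGLE[[missing]]), 1.167))
    dev_r <- if (both_arms)
      list(deviation_mechanism(2L, c(0, DEV_TERM_THREE_V2[[v2]]), 0.005),
           deviation_mechanism(3L, c(0, DEV_TERM_SINGLE[[missing]]), 1.167))
  }
  scenario(mu_r, mu_a, sigma, n_per_arm = n_per_arm, dev_active = dev_a,
           dev_reference = dev_r, truth = truth,
           label = sprintf("row%d_%s_%spct%s", row,
                           if (followups == 1L) "single" else "three",
                           missing, if (both_arms) "_both" else ""))
}

#' Generate complete on-treatment data from the probit model
#'
#' Draws latent rows from `N(mu_t, sigma)` per arm and sets `Y = 1` iff the
#' latent value is `<= 0`. The latent matrix is retained (attribute
#' `"latent"`) so that post-deviation truth can later be regenerated
#' conditionally on the pre-deviation latents.
#'
#' @param scn A [scenario()].
#' @param seed Optional seed.
#' @return A complete [trial_data] object with a `"latent"` attribute.
#' @export
generate_on_treatment <- function(scn, seed = NULL) {
  stopifnot(inherits(scn, "scenario"))
  set_seed_if(seed)
  n <- scn$n_per_arm
  za <- rmvn(n, scn$mu_a, scn$sigma)
  zr <- rmvn(n, scn$mu_r, scn$sigma)
  z <- rbind(za, zr)
  y <- (z <= 0) * 1
  trial_data(y, rep(c("active", "reference"), each = n),
             id = c(sprintf("a%04d", seq_len(n)), sprintf("r%04d", seq_len(n))),
             latent = z)
}

#' Impose MAR deviation via the logistic mechanisms
#'
#' For each arm's deviation mechanisms (in visit order) draws an on-treatment
#' indicator `R ~ Bernoulli(plogis(sum(intercepts) + slope * y1))`; deviation
#' at a visit forces deviation at all later visits, so the resulting
#' deviation times are monotone by construction.
#'
#' @param data Complete [trial_data] from [generate_on_treatment()].
#' @param scn The generating [scenario()].
#' @param seed Optional seed.
#' @return Integer vector of deviation times (last observed visit).
#' @export
impose_deviation <- function(data, scn, seed = NULL) {
  stopifnot(inherits(data, "trial_data"), inherits(scn, "scenario"))
  set_seed_if(seed)
  n <- nrow(data$y)
  p <- data$J_plus_1
  y1 <- data$y[, 1L]
  d <- rep.int(p, n)
  for (a in c("active", "reference")) {
    mechs <- if (a == "active") scn$dev_active else scn$dev_reference
    if (is.null(mechs) || !length(mechs)) next
    rows <- which(data$arm == a)
    mechs <- mechs[order(vapply(mechs, `[[`, 0L, "visit"))]
    for (mech in mechs) {
      lp <- sum(mech$intercepts) + mech$slope * y1[rows]
      r <- stats::rbinom(length(rows), 1L, stats::plogis(lp))
      # deviation at an earlier visit already implies deviation here
      newly <- r == 0L & d[rows] >= mech$visit
      d[rows[newly]] <- mech$visit - 1L
    }
  }
  storage.mode(d) <- "integer"
  names(d) <- data$id
  d
}

#' Regenerate post-deviation outcomes under a reference-based truth
#'
#' Replaces each deviating patient's post-deviation data by draws from the
#' truth-specific conditional normal of the latent variables given the
#' patient's retained pre-deviation latents, using the known true generating
#' parameters, then decodes to binary by the sign rule. Reference-arm
#' patients are always regenerated under their own-arm (randomized-arm MAR)
#' distribution. Completers are untouched. With `truth = "MAR"` the
#' regenerated data are equal in distribution to the original on-treatment
#' data.
#'
#' @param data Complete [trial_data] with a `"latent"` attribute.
#' @param d Deviation times from [impose_deviation()].
#' @param truth Assumption for the active arm's post-deviation behaviour.
#' @param scn The generating [scenario()] (true parameters).
#' @param seed Optional seed.
#' @return A complete [trial_data] with regenerated post-deviation outcomes.
#' @export
regenerate_post_deviation <- function(data, d, truth, scn, seed = NULL) {
  truth <- match_assumption(truth)
  z <- attr(data, "latent")
  if (is.null(z)) stop("latent values required (generate with generate_on_treatment)",
                       call. = FALSE)
  set_seed_if(seed)
  p <- data$J_plus_1
  y <- data$y
  for (a in c("active", "reference")) {
    assum <- if (a == "active") truth else "MAR"
    for (dd in sort(unique(d[data$arm == a & d < p]))) {
      idx <- which(data$arm == a & d == dd)
      joint <- build_joint(assum, a, scn$mu_a, scn$sigma, scn$mu_r, scn$sigma, dd)
      pre <- seq_len(dd); post <- seq.int(dd + 1L, p)
      S11 <- joint$sigma_star[pre, pre, drop = FALSE]
      S12 <- joint$sigma_star[pre, post, drop = FALSE]
      S22 <- joint$sigma_star[post, post, drop = FALSE]
      B <- solve(S11, S12)
      cm <- rep(joint$mu_star[post], each = length(idx)) +
        sweep(z[idx, pre, drop = FALSE], 2L, joint$mu_star[pre]) %*% B
      U <- chol(sym(S22 - crossprod(S12, B)))
      znew <- cm + matrix(stats::rnorm(length(idx) * length(post)),
                          length(idx), length(post)) %*% U
      z[idx, post] <- znew
      y[idx, post] <- (znew <= 0) * 1
    }
  }
  trial_data(y, data$arm, data$id, latent = z)
}

#' Large-sample true treatment effect under a reference-based truth
#'
#' Simulates a very large trial (default one million patients per arm) from
#' the scenario's probit model, imposes the deviation mechanisms, regenerates
#' post-deviation data under the truth assumption with the known parameters,
#' and fits the substantive logistic model to the complete regenerated data.
#'
#' @param scn A [scenario()].
#' @param truth Truth assumption (defaults to the scenario's).
#' @param n Patients per arm for the approximation.
#' @param seed Optional seed.
#' @return The true log odds ratio (active vs reference) at the final visit.
#' @export
compute_true_log_or <- function(scn, truth = scn$truth, n = 1e6, seed = NULL) {
  set_seed_if(seed)
  big <- scn
  big$n_per_arm <- as.integer(n)
  data <- generate_on_treatment(big)
  d <- impose_deviation(data, big)
  regen <- regenerate_post_deviation(data, d, truth, big)
  fit_logistic(regen)$estimate
}

#' Monte-Carlo standard error of a simulation performance estimate
#'
#' `sqrt(variance / n_sim)`, the sampling uncertainty of a mean over `n_sim`
#' simulation replicates of an estimator with the given variance.
#'
#' @param variance Variance of the estimator across replicates.
#' @param n_sim Number of replicates.
#' @return The Monte-Carlo standard error.
#' @examples
#' mcse(0.126, 1000)  # 0.0112
#' @export
mcse <- function(variance, n_sim) {
  stopifnot(variance >= 0, n_sim > 0)
  sqrt(variance / n_sim)
}

#' Information-anchored variance
#'
#' `v_obs_mar / v_full * v_full_reference`: the variance whose proportional
#' inflation over the fully observed reference-based variance equals the
#' inflation of the MAR analysis over the fully observed on-treatment
#' variance.
#'
#' @param v_obs_mar Variance of the treatment effect after imputing the
#'   missing data under MAR.
#' @param v_full Variance with fully observed on-treatment data.
#' @param v_full_reference Variance with fully observed reference-based
#'   post-deviation behaviour.
#' @return The anchored variance.
#' @export
anchored_variance <- function(v_obs_mar, v_full, v_full_reference) {
  stopifnot(v_obs_mar > 0, v_full > 0, v_full_reference > 0)
  v_obs_mar / v_full * v_full_reference
}

#' Run a simulation scenario
#'
#' For each replicate: generate complete on-treatment data, impose deviation,
#' record the full-data variance, regenerate the post-deviation truth(s) and
#' record the fully observed reference-based variance, mask post-deviation
#' data, fit each imputation model once per method (fits are shared across
#' assumptions) and impute/pool under every requested assumption. Aggregates
#' bias against the large-sample true value, empirical and mean Rubin
#' variance, coverage of the 95% intervals, Monte-Carlo standard errors and
#' the information-anchored variance (available when `"MAR"` is among the
#' assumptions).
#'
#' @param scn A [scenario()]; its `truth` may be a character vector, in which
#'   case every truth is evaluated against every assumption.
#' @param methods Subset of `c("mvn_rounding", "latent")`.
#' @param assumptions Imputation assumptions to run.
#' @param n_sim Number of replicates (`>= 2`).
#' @param K Imputations per replicate.
#' @param config A [sampler_config()] (seed ignored; substreams are derived
#'   from `seed`).
#' @param n_true Patients per arm for the large-sample true values.
#' @param seed Master seed; every random component consumes a substream.
#' @param engine MCMC engine.
#' @param verbose Print progress every 25 replicates.
#' @return A `performance_table` data frame with one row per
#'   (method, assumption, truth).
#' @export
run_scenario <- function(scn, methods = c("mvn_rounding", "latent"),
                         assumptions = c("MAR", "CR"), n_sim = 200L, K = 50L,
                         config = sampler_config(n_draws = K), n_true = 1e6,
                         seed = 1L, engine = "cpp", verbose = FALSE) {
  stopifnot(inherits(scn, "scenario"), n_sim >= 2L)
  methods <- match.arg(methods, c("mvn_rounding", "latent"), several.ok = TRUE)
  assumptions <- vapply(assumptions, match_assumption, "")
  truths <- vapply(scn$truth, match_assumption, "")
  config$n_draws <- as.integer(K)

  true_lor <- vapply(seq_along(truths), function(i) {
    compute_true_log_or(scn, truths[i], n = n_true,
                        seed = substream_seed(seed, 900000L, i))
  }, 0)
  names(true_lor) <- truths

  est <- tvar <- cil <- cih <- array(
    NA_real_, c(n_sim, length(methods), length(assumptions)),
    dimnames = list(NULL, methods, assumptions))
  v_full <- rep(NA_real_, n_sim)
  v_full_ref <- matrix(NA_real_, n_sim, length(truths),
                       dimnames = list(NULL, truths))
  n_sep <- matrix(0L, length(methods), length(assumptions),
                  dimnames = list(methods, assumptions))

  for (r in seq_len(n_sim)) {
    sr <- substream_seed(seed, r)
    data <- generate_on_treatment(scn, seed = substream_seed(sr, 1L))
    v_full[r] <- tryCatch(fit_logistic(data)$variance, error = function(e) NA_real_)
    d <- impose_deviation(data, scn, seed = substream_seed(sr, 2L))
    for (i in seq_along(truths)) {
      regen <- regenerate_post_deviation(data, d, truths[i], scn,
                                         seed = substream_seed(sr, 3L, i))
      v_full_ref[r, i] <- tryCatch(fit_logistic(regen)$variance,
                                   error = function(e) NA_real_)
    }
    masked <- mask_post_deviation(data, d)
    for (m in seq_along(methods)) {
      fit_fun <- if (methods[m] == "mvn_rounding") draw_mvn_posterior else gibbs_latent_fit
      draws <- list()
      for (a in c("active", "reference")) {
        cfg <- config
        cfg$seed <- substream_seed(sr, 4L, m, match(a, c("active", "reference")))
        draws[[a]] <- fit_fun(masked$y[masked$arm == a, , drop = FALSE], cfg,
                              engine = engine)
      }
      for (s in seq_along(assumptions)) {
        pooled <- tryCatch({
          stack <- if (methods[m] == "mvn_rounding") {
            impute_mvn_rounding(masked, assumptions[s], K = K, config = config,
                                draws = draws, seed = substream_seed(sr, 5L, m, s))
          } else {
            impute_latent(masked, assumptions[s], K = K, config = config,
                          draws = draws, seed = substream_seed(sr, 5L, m, s))
          }
          pool_imputations(stack, on_separation = "drop")
        }, error = function(e) NULL)
        if (is.null(pooled)) {
          n_sep[m, s] <- n_sep[m, s] + 1L
        } else {
          est[r, m, s] <- pooled$qbar
          tvar[r, m, s] <- pooled$t_var
          cil[r, m, s] <- pooled$ci_low
          cih[r, m, s] <- pooled$ci_high
        }
      }
    }
    if (verbose && r %% 25L == 0L) message("replicate ", r, "/", n_sim)
  }

  rows <- list()
  for (m in seq_along(methods)) {
    mar_var <- if ("MAR" %in% assumptions)
      mean(tvar[, m, "MAR"], na.rm = TRUE) else NA_real_
    for (s in seq_along(assumptions)) {
      ok <- !is.na(est[, m, s])
      e <- est[ok, m, s]
      for (i in seq_along(truths)) {
        cov <- mean(cil[ok, m, s] <= true_lor[i] & cih[ok, m, s] >= true_lor[i])
        anch <- if (is.na(mar_var)) NA_real_ else
          anchored_variance(mar_var, mean(v_full, na.rm = TRUE),
                            mean(v_full_ref[, i], na.rm = TRUE))
        rows[[length(rows) + 1L]] <- data.frame(
          scenario = scn$label, method = methods[m],
          assumption = assumptions[s], truth = truths[i],
          n_sim = sum(ok), n_dropped = n_sep[m, s],
          true_log_or = unname(true_lor[i]), mean_est = mean(e),
          bias = mean(e) - true_lor[i],
          empirical_var = stats::var(e),
          mean_model_var = mean(tvar[ok, m, s]),
          anchored_var = anch,
          mean_v_full = mean(v_full, na.rm = TRUE),
          mean_v_full_reference = mean(v_full_ref[, i], na.rm = TRUE),
          mean_v_obs_mar = mar_var,
          coverage = cov,
          mcse = mcse(stats::var(e), sum(ok)))
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("performance_table", "data.frame")
  out
}
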