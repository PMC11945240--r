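new_meta_result <- function(pooled_log_ratio, se_log, level, z, numerator,
                            denominator, model, k, q_stat, tau2, i2, weights,
                            studies) {
  out <- new_ratio_estimate(pooled_log_ratio, se_log, level, z,
                            numerator, denominator,
                            provenance = list(type = "pooled", model = model,
                                              k = k))
  out$pooled_log_ratio <- pooled_log_ratio
  out$model <- model
  out$k <- k
  out$q_stat <- q_stat
  out$tau2 <- tau2
  out$i2 <- i2
  out$weights <- weights
  out$studies <- studies
  class(out) <- c("meta_result", "ratio_estimate")
  out
}

check_pool_input <- function(estimates) {
  if (!is.list(estimates) || length(estimates) < 1L)
    am_stop_validation("estimates must be a non-empty list of ratio_estimate objects")
  ok <- vapply(estimates, inherits, logical(1), what = "ratio_estimate")
  if (!all(ok))
    am_stop_validation("every element of estimates must be a ratio_estimate")
  nums <- vapply(estimates, `[[`, character(1), "numerator")
  dens <- vapply(estimates, `[[`, character(1), "denominator")
  if (length(unique(nums)) != 1L || length(unique(dens)) != 1L)
    am_stop_validation(sprintf(
      "all estimates must compare the same arms; found %s",
      paste(unique(paste(nums, "vs.", dens)), collapse = "; ")))
  invisible(NULL)
}

study_labels <- function(estimates) {
  vapply(seq_along(estimates), function(i) {
    id <- estimates[[i]]$provenance$trial_id
    if (is.null(id)) sprintf("study %d", i) else id
  }, character(1))
}

meta_study_frame <- function(estimates) {
  data.frame(label = study_labels(estimates),
             ratio = vapply(estimates, `[[`, numeric(1), "ratio"),
             se_log = vapply(estimates, `[[`, numeric(1), "se_log"),
             ci_lower = vapply(estimates, `[[`, numeric(1), "ci_lower"),
             ci_upper = vapply(estimates, `[[`, numeric(1), "ci_upper"),
             stringsAsFactors = FALSE)
}

#' Common-effect inverse-variance pooling of rate ratios
#'
#' Pools log rate ratios with weights `w_i = 1 / se_i^2`; the pooled log
#' ratio is the weighted mean and its SE is `sqrt(1 / sum(w))`. Cochran's Q
#' and I-squared are reported as heterogeneity descriptives.
#'
#' @param estimates List of `ratio_estimate` objects for the same comparison.
#' @param level Confidence level (default 0.95).
#' @param z Optional critical value; see [z_multiplier()].
#' @return A `meta_result` (also a `ratio_estimate`) with fields `model`
#'   (`"common_iv"`), `q_stat`, `tau2` (0), `i2`, normalized `weights`, and
#'   a per-study `studies` data frame.
#' @export
pool_common_iv <- function(estimates, level = 0.95, z = NULL) {
  check_pool_input(estimates)
  zc <- z_multiplier(level, z)
  theta <- vapply(estimates, `[[`, numeric(1), "log_ratio")
  se <- vapply(estimates, `[[`, numeric(1), "se_log")
  w <- 1 / se^2
  pooled <- sum(w * theta) / sum(w)
  q <- sum(w * (theta - pooled)^2)
  df <- length(theta) - 1L
  i2 <- if (df > 0 && q > 0) max(0, (q - df) / q) else 0
  new_meta_result(pooled, sqrt(1 / sum(w)), level, zc,
                  numerator = estimates[[1]]$numerator,
                  denominator = estimates[[1]]$denominator,
                  model = "common_iv", k = length(theta),
                  q_stat = q, tau2 = 0, i2 = i2,
                  weights = stats::setNames(w / sum(w), study_labels(estimates)),
                  studies = meta_study_frame(estimates))
}

#' DerSimonian-Laird random-effects pooling of rate ratios
#'
#' Moment-based random-effects model: the between-study variance is
#' estimated from the common-effect (inverse-variance) Q statistic as
#' `tau2 = max(0, (Q - df) / C)` with `C = sum(w) - sum(w^2)/sum(w)`, then
#' studies are re-weighted by `1 / (se_i^2 + tau2)`. The pooled CI uses the
#' normal approximation. With a single study the input is returned with
#' `tau2 = 0`; when `tau2` truncates to 0 the result equals the
#' common-effect answer.
#'
#' @inheritParams pool_common_iv
#' @return A `meta_result` with `model = "random_dl"` and positive `tau2`
#'   when heterogeneity exceeds its sampling expectation.
#' @examples
#' tr <- case_study_trials()
#' ests <- list(trial_ratio(tr$trial2, "Anchor", "Placebo"),
#'              trial_ratio(tr$trial3, "Anchor", "Placebo"))
#' pool_random_dl(ests)  # pooled ratio 3.382, SE 0.275
#' @export
pool_random_dl <- function(estimates, level = 0.95, z = NULL) {
  check_pool_input(estimates)
  zc <- z_multiplier(level, z)
  theta <- vapply(estimates, `[[`, numeric(1), "log_ratio")
  se <- vapply(estimates, `[[`, numeric(1), "se_log")
  w <- 1 / se^2
  pooled_fe <- sum(w * theta) / sum(w)
  q <- sum(w * (theta - pooled_fe)^2)
  df <- length(theta) - 1L
  if (df > 0) {
    cval <- sum(w) - sum(w^2) / sum(w)
    tau2 <- max(0, (q - df) / cval)
    i2 <- if (q > 0) max(0, (q - df) / q) else 0
  } else {
    tau2 <- 0
    i2 <- 0
  }
  wstar <- 1 / (se^2 + tau2)
  pooled <- sum(wstar * theta) / sum(wstar)
  new_meta_result(pooled, sqrt(1 / sum(wstar)), level, zc,
                  numerator = estimates[[1]]$numerator,
                  denominator = estimates[[1]]$denominator,
                  model = "random_dl", k = length(theta),
                  q_stat = q, tau2 = tau2, i2 = i2,
                  weights = stats::setNames(wstar / sum(wstar),
                                            study_labels(estimates)),
                  studies = meta_study_frame(estimates))
}

#' Mantel-Haenszel common-effect pooled rate ratio
#'
#' Count-based common-effect pooling: the Mantel-Haenszel rate ratio with
#' the Greenland-Robins variance for its logarithm, computed via
#' [metafor::rma.mh()] on the raw 2x2 tables (no continuity corrections are
#' applied — MH pooling does not need them unless a stratum is degenerate).
#'
#' @param trials List of [two_arm_trial()] objects, each containing both the
#'   numerator and the denominator arm.
#' @param numerator_label,denominator_label Arm labels defining the ratio.
#' @param level Confidence level (default 0.95).
#' @param z Optional critical value; see [z_multiplier()].
#' @return A `meta_result` with `model = "common_mh"` and Mantel-Haenszel
#'   per-study weights.
#' @export
pool_common_mh <- function(trials, numerator_label, denominator_label,
                           level = 0.95, z = NULL) {
  if (!is.list(trials) || length(trials) < 1L)
    am_stop_validation("trials must be a non-empty list of two_arm_trial objects")
  ok <- vapply(trials, inherits, logical(1), what = "two_arm_trial")
  if (!all(ok))
    am_stop_validation(paste0(
      "Mantel-Haenszel pooling needs full 2x2 counts: every element must be ",
      "a two_arm_trial (summary-only ratio estimates are not enough)"))
  zc <- z_multiplier(level, z)
  num <- lapply(trials, trial_arm, label = numerator_label)
  den <- lapply(trials, trial_arm, label = denominator_label)
  ai <- vapply(num, `[[`, integer(1), "responders")
  n1 <- vapply(num, `[[`, integer(1), "n")
  ci <- vapply(den, `[[`, integer(1), "responders")
  n2 <- vapply(den, `[[`, integer(1), "n")
  fit <- metafor::rma.mh(ai = ai, bi = n1 - ai, ci = ci, di = n2 - ci,
                         measure = "RR", add = 0, to = "none",
                         correct = FALSE, level = 100 * level)
  mh_w <- ci * n1 / (n1 + n2)
  labels <- vapply(trials, `[[`, character(1), "trial_id")
  ests <- lapply(trials, trial_ratio,
                 numerator_label = numerator_label,
                 denominator_label = denominator_label,
                 level = level, z = zc)
  new_meta_result(as.numeric(fit$beta), fit$se, level, zc,
                  numerator = numerator_label,
                  denominator = denominator_label,
                  model = "common_mh", k = length(trials),
                  q_stat = as.numeric(fit$QE), tau2 = 0,
                  i2 = if (length(trials) > 1L && fit$QE > 0)
                    max(0, (fit$QE - (length(trials) - 1L)) / fit$QE) else 0,
                  weights = stats::setNames(mh_w / sum(mh_w), labels),
                  studies = meta_study_frame(ests))
}

#' Forest-plot data export
#'
#' Plot-ready forest data: one row per study plus pooled common-effect and
#' random-effects rows, with both weighting schemes. No graphics are drawn.
#'
#' @param estimates List of `ratio_estimate` objects for one comparison.
#' @param level Confidence level (default 0.95).
#' @param z Optional critical value.
#' @return Data frame with columns `label`, `ratio`, `ci_lower`, `ci_upper`,
#'   `weight_common`, `weight_random`.
#' @export
forest_data <- function(estimates, level = 0.95, z = NULL) {
  fe <- pool_common_iv(estimates, level = level, z = z)
  re <- pool_random_dl(estimates, level = level, z = z)
  studies <- fe$studies
  out <- data.frame(label = studies$label,
                    ratio = studies$ratio,
                    ci_lower = studies$ci_lower,
                    ci_upper = studies$ci_upper,
                    weight_common = as.numeric(fe$weights),
                    weight_random = as.numeric(re$weights),
                    stringsAsFactors = FALSE)
  pooled <- data.frame(
    label = c("Pooled (common effect)", "Pooled (random effects)"),
    ratio = c(fe$ratio, re$ratio),
    ci_lower = c(fe$ci_lower, re$ci_lower),
    ci_upper = c(fe$ci_upper, re$ci_upper),
    weight_common = c(1, NA_real_),
    weight_random = c(NA_real_, 1),
    stringsAsFactors = FALSE)
  rbind(out, pooled)
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf(
    "%s vs. %s pooled over %d studies [%s]: ratio %.3f, SE(ln) %.3f, %d%% CI (%.3f, %.3f)\n",
    x$numerator, x$denominator, x$k, x$model, x$ratio, x$se_log,
    round(100 * x$level), x$ci_lower, x$ci_upper))
  cat(sprintf("  Q = %.3f, tau^2 = %.4f, I^2 = %.1f%%\n",
              x$q_stat, x$tau2, 100 * x$i2))
  invisible(x)
}
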