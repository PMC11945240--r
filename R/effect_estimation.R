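new_ratio_estimate <- function(log_ratio, se_log, level, z, numerator,
                               denominator, provenance) {
  structure(list(ratio = exp(log_ratio),
                 log_ratio = log_ratio,
                 se_log = se_log,
                 ci_lower = exp(log_ratio - z * se_log),
                 ci_upper = exp(log_ratio + z * se_log),
                 level = level, z = z,
                 numerator = numerator, denominator = denominator,
                 provenance = provenance),
            class = "ratio_estimate")
}

#' Direct within-trial response-rate ratio
#'
#' Estimates the ratio of response rates between two arms of the same trial,
#' with the delta-method standard error of the log ratio
#' `sqrt(1/r1 + 1/r2 - 1/n1 - 1/n2)` (where `r` are responder counts and `n`
#' participant counts) and a log-scale Wald confidence interval
#' `exp(ln(ratio) +/- z * SE)`.
#'
#' The SE formula is undefined when either arm has zero responders. By
#' default this is an error; `correction = TRUE` opts into the standard
#' continuity correction that adds 0.5 to every cell of the 2x2 table
#' (responders and non-responders of both arms) before estimation.
#'
#' @param numerator,denominator [make_arm()] objects; the ratio is
#'   numerator rate over denominator rate.
#' @param level Confidence level (default 0.95).
#' @param z Optional critical value; see [z_multiplier()].
#' @param correction Apply a 0.5 continuity correction to all four cells
#'   (default `FALSE`).
#' @param trial_id Optional trial identifier recorded in the provenance.
#' @return A `ratio_estimate` with fields `ratio`, `log_ratio`, `se_log`,
#'   `ci_lower`, `ci_upper`, `level`, `z`, `numerator`, `denominator`,
#'   `provenance`.
#' @examples
#' trial1 <- case_study_trials()$trial1
#' direct_ratio(trial_arm(trial1, "Anchor"), trial_arm(trial1, "Reference"))
#' @export
direct_ratio <- function(numerator, denominator, level = 0.95, z = NULL,
                         correction = FALSE, trial_id = NULL) {
  if (!inherits(numerator, "arm_summary") || !inherits(denominator, "arm_summary"))
    am_stop_validation("numerator and denominator must be arm_summary objects")
  zc <- z_multiplier(level, z)
  r1 <- numerator$responders
  r2 <- denominator$responders
  n1 <- numerator$n
  n2 <- denominator$n
  if (correction) {
    r1 <- r1 + 0.5; r2 <- r2 + 0.5
    n1 <- n1 + 1; n2 <- n2 + 1
  } else if (numerator$responders == 0L || denominator$responders == 0L) {
    am_stop_validation(paste0(
      "zero responders in arm '",
      if (numerator$responders == 0L) numerator$label else denominator$label,
      "': the log rate-ratio SE is undefined; rerun with correction = TRUE ",
      "(adds 0.5 to all four cells) or use an exact method"))
  }
  log_ratio <- log((r1 / n1) / (r2 / n2))
  se_log <- sqrt(1 / r1 + 1 / r2 - 1 / n1 - 1 / n2)
  new_ratio_estimate(log_ratio, se_log, level, zc,
                     numerator = numerator$label,
                     denominator = denominator$label,
                     provenance = list(type = "direct", trial_id = trial_id))
}

#' Direct rate ratio between two labelled arms of one trial
#'
#' Convenience wrapper around [direct_ratio()] that pulls arms from a
#' [two_arm_trial()] by label and records the trial id.
#'
#' @param trial A [two_arm_trial()].
#' @param numerator_label,denominator_label Arm labels.
#' @inheritParams direct_ratio
#' @return A `ratio_estimate`.
#' @export
trial_ratio <- function(trial, numerator_label, denominator_label,
                        level = 0.95, z = NULL, correction = FALSE) {
  direct_ratio(trial_arm(trial, numerator_label),
               trial_arm(trial, denominator_label),
               level = level, z = z, correction = correction,
               trial_id = trial$trial_id)
}

#' Anchor-based indirect comparison
#'
#' Bridges two comparisons that share a common anchor treatment: from
#' Anchor-vs-Target (e.g. Anchor vs Reference) and Anchor-vs-Comparator
#' (e.g. Anchor vs Placebo), the Target-vs-Comparator effect is estimated on
#' the log scale as the difference of the two log ratios, and its variance
#' as the sum of the two variances. Both inputs must have the same anchor
#' (numerator) label; this guards the transitivity bridge.
#'
#' @param anchor_vs_target `ratio_estimate` for Anchor vs the treatment that
#'   becomes the numerator of the result (Reference in the biosimilar case).
#' @param anchor_vs_comparator `ratio_estimate` for Anchor vs the treatment
#'   that becomes the denominator (Placebo). May be a pooled `meta_result`.
#' @param level Confidence level for the result (default 0.95).
#' @param z Optional critical value; see [z_multiplier()].
#' @return A `ratio_estimate` with `provenance$type == "indirect"`.
#' @examples
#' tr <- case_study_trials()
#' avr <- trial_ratio(tr$trial1, "Anchor", "Reference")
#' avp <- trial_ratio(tr$trial2, "Anchor", "Placebo")
#' indirect_ratio(avr, avp)  # Reference vs Placebo, ratio 2.586
#' @export
indirect_ratio <- function(anchor_vs_target, anchor_vs_comparator,
                           level = 0.95, z = NULL) {
  if (!inherits(anchor_vs_target, "ratio_estimate") ||
      !inherits(anchor_vs_comparator, "ratio_estimate"))
    am_stop_validation("both inputs must be ratio_estimate objects")
  if (!identical(anchor_vs_target$numerator, anchor_vs_comparator$numerator))
    am_stop_validation(sprintf(
      "anchor labels differ ('%s' vs '%s'): both comparisons must share the same anchor",
      anchor_vs_target$numerator, anchor_vs_comparator$numerator))
  zc <- z_multiplier(level, z)
  log_ratio <- anchor_vs_comparator$log_ratio - anchor_vs_target$log_ratio
  se_log <- sqrt(anchor_vs_target$se_log^2 + anchor_vs_comparator$se_log^2)
  new_ratio_estimate(log_ratio, se_log, level, zc,
                     numerator = anchor_vs_target$denominator,
                     denominator = anchor_vs_comparator$denominator,
                     provenance = list(
                       type = "indirect",
                       anchor = anchor_vs_target$numerator,
                       components = list(anchor_vs_target$provenance,
                                         anchor_vs_comparator$provenance)))
}

#' Invert the direction of a ratio estimate
#'
#' Maps a comparison A vs B to B vs A: the ratio becomes its reciprocal, the
#' SE is unchanged, and the CI bounds swap and invert.
#'
#' @param estimate A `ratio_estimate`.
#' @return A `ratio_estimate` in the opposite direction.
#' @export
invert_ratio <- function(estimate) {
  if (!inherits(estimate, "ratio_estimate"))
    am_stop_validation("estimate must be a ratio_estimate")
  new_ratio_estimate(-estimate$log_ratio, estimate$se_log,
                     estimate$level, estimate$z,
                     numerator = estimate$denominator,
                     denominator = estimate$numerator,
                     provenance = estimate$provenance)
}

#' @export
print.ratio_estimate <- function(x, ...) {
  cat(sprintf("%s vs. %s [%s]: ratio %.3f, SE(ln) %.3f, %d%% CI (%.3f, %.3f)\n",
              x$numerator, x$denominator, x$provenance$type,
              x$ratio, x$se_log, round(100 * x$level),
              x$ci_lower, x$ci_upper))
  invisible(x)
}

#' Tabulate ratio estimates
#'
#' @param x A `ratio_estimate`.
#' @param ... Unused.
#' @return One-row data frame with comparison, ratio, SE and CI columns.
#' @export
as.data.frame.ratio_estimate <- function(x, ...) {
  data.frame(comparison = paste(x$numerator, "vs.", x$denominator),
             provenance = x$provenance$type,
             ratio = x$ratio, se_log = x$se_log,
             ci_lower = x$ci_lower, ci_upper = x$ci_upper,
             stringsAsFactors = FALSE)
}
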