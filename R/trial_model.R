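#' @keywords internal
"_PACKAGE"

## Structured error conditions so the CLI can map failures to exit codes:
## validation errors (bad input) vs. scientific non-results (no demonstrated
## effect, hence no margin).
am_stop <- function(msg, class) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

am_stop_validation <- function(msg) am_stop(msg, "anchormargin_validation_error")
am_stop_no_effect <- function(msg) am_stop(msg, "anchormargin_no_effect_error")

#' Critical value used for confidence intervals
#'
#' The package follows the reporting convention of using 1.96 exactly for
#' 95% intervals (rather than the exact normal quantile 1.959964); any other
#' confidence level falls back to `qnorm((1 + level) / 2)`. Supplying `z`
#' overrides both.
#'
#' @param level Two-sided confidence level in (0, 1).
#' @param z Optional explicit multiplier; returned unchanged when given.
#' @return A positive scalar multiplier.
#' @export
z_multiplier <- function(level = 0.95, z = NULL) {
  if (!is.null(z)) {
    if (!is.numeric(z) || length(z) != 1L || z <= 0)
      am_stop_validation("z must be a single positive number")
    return(z)
  }
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1)
    am_stop_validation("level must be a single number strictly between 0 and 1")
  if (identical(level, 0.95)) 1.96 else stats::qnorm((1 + level) / 2)
}

#' Construct a trial-arm summary
#'
#' An arm summary holds the label, number of participants, number of
#' responders and the derived response rate for one arm of a binomial trial.
#'
#' @param label Arm label, e.g. `"Anchor"`, `"Reference"`, `"Placebo"`.
#' @param n Number of participants (positive integer).
#' @param responders Number of responders (integer, `0 <= responders <= n`).
#' @return An object of class `arm_summary` with fields `label`, `n`,
#'   `responders` and `rate` (= `responders / n`, carried at full precision).
#' @examples
#' make_arm("Reference", 200, 85)$rate  # 0.425
#' @export
make_arm <- function(label, n, responders) {
  if (!is.character(label) || length(label) != 1L || !nzchar(label))
    am_stop_validation("label must be a non-empty character scalar")
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1 || n != as.integer(n))
    am_stop_validation(sprintf("n must be a positive integer (arm '%s')", label))
  if (!is.numeric(responders) || length(responders) != 1L || is.na(responders) ||
      responders < 0 || responders != as.integer(responders))
    am_stop_validation(sprintf("responders must be a non-negative integer (arm '%s')", label))
  if (responders > n)
    am_stop_validation(sprintf("responders (%d) exceeds n (%d) in arm '%s'",
                               as.integer(responders), as.integer(n), label))
  structure(list(label = label, n = as.integer(n),
                 responders = as.integer(responders),
                 rate = responders / n),
            class = "arm_summary")
}

#' @export
print.arm_summary <- function(x, ...) {
  cat(sprintf("%s: %d/%d responders (rate %.3f)\n",
              x$label, x$responders, x$n, x$rate))
  invisible(x)
}

#' Construct a two-arm trial
#'
#' @param trial_id Trial identifier.
#' @param arm_a,arm_b [make_arm()] objects with distinct labels.
#' @return An object of class `two_arm_trial` with fields `trial_id` and
#'   `arms` (a named list keyed by arm label).
#' @examples
#' two_arm_trial("Trial 1", make_arm("Anchor", 200, 94),
#'               make_arm("Reference", 200, 85))
#' @export
two_arm_trial <- function(trial_id, arm_a, arm_b) {
  if (!is.character(trial_id) || length(trial_id) != 1L || !nzchar(trial_id))
    am_stop_validation("trial_id must be a non-empty character scalar")
  if (!inherits(arm_a, "arm_summary") || !inherits(arm_b, "arm_summary"))
    am_stop_validation("arm_a and arm_b must be arm_summary objects")
  if (identical(arm_a$label, arm_b$label))
    am_stop_validation(sprintf("arm labels must be distinct in trial '%s'", trial_id))
  arms <- list(arm_a, arm_b)
  names(arms) <- c(arm_a$label, arm_b$label)
  structure(list(trial_id = trial_id, arms = arms), class = "two_arm_trial")
}

#' @export
print.two_arm_trial <- function(x, ...) {
  cat(sprintf("%s:\n", x$trial_id))
  for (a in x$arms)
    cat(sprintf("  %s: %d/%d (rate %.3f)\n", a$label, a$responders, a$n, a$rate))
  invisible(x)
}

#' Extract an arm from a trial by label
#'
#' @param trial A [two_arm_trial()].
#' @param label Arm label to extract.
#' @return The matching `arm_summary`.
#' @export
trial_arm <- function(trial, label) {
  if (!inherits(trial, "two_arm_trial"))
    am_stop_validation("trial must be a two_arm_trial")
  a <- trial$arms[[label]]
  if (is.null(a))
    am_stop_validation(sprintf("trial '%s' has no arm labelled '%s' (arms: %s)",
                               trial$trial_id, label,
                               paste(names(trial$arms), collapse = ", ")))
  a
}

#' Wald confidence interval for a response rate
#'
#' Computes `rate +/- z * sqrt(rate * (1 - rate) / n)`. By default the
#' interval is not truncated to \[0, 1\]: small arms with low rates can yield
#' lower bounds near (or below) zero, and the untruncated bound is what is
#' conventionally reported alongside the raw rate.
#'
#' @param arm An [make_arm()] object.
#' @param level Confidence level (default 0.95).
#' @param z Optional critical value; see [z_multiplier()].
#' @param clip If `TRUE`, truncate the bounds to \[0, 1\]. Default `FALSE`.
#' @return An object of class `rate_ci` with fields `rate`, `lower`, `upper`,
#'   `level`.
#' @examples
#' wald_rate_ci(make_arm("Reference", 200, 85))  # (0.356, 0.494)
#' @export
wald_rate_ci <- function(arm, level = 0.95, z = NULL, clip = FALSE) {
  if (!inherits(arm, "arm_summary"))
    am_stop_validation("arm must be an arm_summary")
  zc <- z_multiplier(level, z)
  half <- zc * sqrt(arm$rate * (1 - arm$rate) / arm$n)
  lo <- arm$rate - half
  hi <- arm$rate + half
  if (clip) {
    lo <- max(0, lo)
    hi <- min(1, hi)
  }
  structure(list(rate = arm$rate, lower = lo, upper = hi, level = level),
            class = "rate_ci")
}

#' @export
print.rate_ci <- function(x, ...) {
  cat(sprintf("rate %.3f, %d%% CI (%.3f, %.3f)\n",
              x$rate, round(100 * x$level), x$lower, x$upper))
  invisible(x)
}
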