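new_equivalence_margin <- function(upper, preservation, source_bound, level) {
  structure(list(lower = 1 / upper, upper = upper,
                 preservation = preservation,
                 source_bound = source_bound, level = level),
            class = "equivalence_margin")
}

#' Derive a 95-95 fixed equivalence margin
#'
#' Implements the fixed-margin (95-95) method for a rate-ratio effect: the
#' margin retains a stated fraction (the preservation factor `f`) of the
#' historical effect, measured on the log scale at the confidence-interval
#' bound nearer the null. For an effect with `ci_lower > 1`,
#' `upper = exp(ln(ci_lower) * (1 - f))` and `lower = 1 / upper`, so the
#' margin is symmetric on the log scale.
#'
#' If the supplied effect points in the protective direction (ratio < 1),
#' it is inverted internally so the bound nearer 1 is used; the margin is
#' direction-free by its log-symmetry. An effect whose CI does not exclude
#' the null (bound `<= 1`) demonstrates no effect, and no margin is defined.
#'
#' @param effect A `ratio_estimate` (its CI bound nearer 1 is used), or a
#'   single number giving that bound directly.
#' @param preservation Fraction of the log effect to preserve, in \[0, 1\].
#' @return An object of class `equivalence_margin` with fields `lower`,
#'   `upper`, `preservation`, `source_bound`, `level`.
#' @examples
#' derive_margin(1.865, 0.60)  # margin (0.779, 1.283)
#' @export
derive_margin <- function(effect, preservation) {
  if (!is.numeric(preservation) || length(preservation) != 1L ||
      is.na(preservation) || preservation < 0 || preservation > 1)
    am_stop_validation("preservation must be a single number in [0, 1]")
  if (inherits(effect, "ratio_estimate")) {
    bound <- if (effect$ratio < 1) 1 / effect$ci_upper else effect$ci_lower
    level <- effect$level
  } else if (is.numeric(effect) && length(effect) == 1L && !is.na(effect) &&
             effect > 0) {
    bound <- if (effect < 1) 1 / effect else effect
    level <- 0.95
  } else {
    am_stop_validation("effect must be a ratio_estimate or a single positive number")
  }
  if (bound <= 1)
    am_stop_no_effect(paste0(
      "no demonstrated effect: the confidence bound nearer 1 is ",
      format(bound), " <= 1, so no equivalence margin is defined"))
  new_equivalence_margin(upper = exp(log(bound) * (1 - preservation)),
                         preservation = preservation,
                         source_bound = bound, level = level)
}

#' Preservation factor achieved by a margin
#'
#' Inverts the fixed-margin formula: given a margin upper bound `m > 1` and
#' an effect CI bound `b > 1`, the fraction of the log effect preserved is
#' `1 - ln(m) / ln(b)`. The value is returned signed: a margin wider than
#' the effect bound preserves a negative fraction, which sensitivity sweeps
#' plot rather than error on.
#'
#' @param margin_upper Margin upper bound (> 1), or an `equivalence_margin`
#'   whose `upper` is used.
#' @param ci_lower The effect's CI bound nearer 1 (must be > 1), or a
#'   `ratio_estimate` whose `ci_lower` is used.
#' @return Signed preservation fraction.
#' @examples
#' preservation_of(1.283, 1.711)  # 0.536
#' @export
preservation_of <- function(margin_upper, ci_lower) {
  if (inherits(margin_upper, "equivalence_margin")) margin_upper <- margin_upper$upper
  if (inherits(ci_lower, "ratio_estimate")) ci_lower <- ci_lower$ci_lower
  if (!is.numeric(margin_upper) || length(margin_upper) != 1L || margin_upper <= 1)
    am_stop_validation("margin_upper must be a single number > 1")
  if (!is.numeric(ci_lower) || length(ci_lower) != 1L || is.na(ci_lower))
    am_stop_validation("ci_lower must be a single number")
  if (ci_lower <= 1)
    am_stop_no_effect("ci_lower <= 1: no demonstrated effect, preservation undefined")
  1 - log(margin_upper) / log(ci_lower)
}

#' Equivalence verdict for a future trial's confidence interval
#'
#' Applies the two-one-sided-tests containment rule: equivalence is met when
#' the treatment-comparison CI lies entirely inside the margin. Containment
#' is strict by default (open interval). A third state flags the case where
#' the CI is inside the margin but excludes the equality point 1 — formally
#' equivalent, but a result that needs additional explanation.
#'
#' @param ci_lower,ci_upper CI bounds of the future trial's rate ratio.
#' @param margin An `equivalence_margin`.
#' @param strict Use strict inequalities for containment (default `TRUE`).
#' @return One of `"met"`, `"not_met"`, `"met_without_equality_point"`.
#' @examples
#' m <- derive_margin(1.865, 0.60)
#' equivalence_verdict(0.85, 1.20, m)   # "met"
#' equivalence_verdict(1.05, 1.25, m)   # "met_without_equality_point"
#' @export
equivalence_verdict <- function(ci_lower, ci_upper, margin, strict = TRUE) {
  if (!inherits(margin, "equivalence_margin"))
    am_stop_validation("margin must be an equivalence_margin")
  if (!is.numeric(ci_lower) || !is.numeric(ci_upper) ||
      length(ci_lower) != 1L || length(ci_upper) != 1L ||
      ci_lower <= 0 || ci_upper <= 0 || ci_lower > ci_upper)
    am_stop_validation("need 0 < ci_lower <= ci_upper")
  inside <- if (strict) {
    margin$lower < ci_lower && ci_upper < margin$upper
  } else {
    margin$lower <= ci_lower && ci_upper <= margin$upper
  }
  if (!inside) return("not_met")
  excludes_one <- ci_lower > 1 || ci_upper < 1
  if (excludes_one) "met_without_equality_point" else "met"
}

#' Margin table over several preservation factors
#'
#' @param effect As in [derive_margin()].
#' @param preservations Vector of preservation fractions
#'   (default `c(0.4, 0.5, 0.6, 0.7)`).
#' @return Data frame with columns `preservation`, `source_bound`,
#'   `margin_lower`, `margin_upper`.
#' @examples
#' tr <- case_study_trials()
#' ind <- indirect_ratio(trial_ratio(tr$trial1, "Anchor", "Reference"),
#'                       trial_ratio(tr$trial2, "Anchor", "Placebo"))
#' margin_table(ind)
#' @export
margin_table <- function(effect, preservations = c(0.4, 0.5, 0.6, 0.7)) {
  rows <- lapply(preservations, function(f) {
    m <- derive_margin(effect, f)
    data.frame(preservation = f, source_bound = m$source_bound,
               margin_lower = m$lower, margin_upper = m$upper)
  })
  do.call(rbind, rows)
}

#' @export
print.equivalence_margin <- function(x, ...) {
  cat(sprintf(
    "Equivalence margin (%.3f, %.3f) preserving %.0f%% of the effect (bound %.3f)\n",
    x$lower, x$upper, 100 * x$preservation, x$source_bound))
  invisible(x)
}
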