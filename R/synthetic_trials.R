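#' Worked case-study trials
#'
#' The three historical trials of the worked biosimilar case study, with the
#' published per-arm counts: Trial 1 compares Anchor (94/200) to Reference
#' (85/200); Trial 2 compares Anchor (183/350) to Placebo (64/350); Trial 3,
#' from a somewhat different population, compares Anchor (53/100) to Placebo
#' (5/50).
#'
#' @return Named list of [two_arm_trial()] objects: `trial1`, `trial2`,
#'   `trial3`.
#' @examples
#' case_study_trials()$trial1
#' @export
case_study_trials <- function() {
  list(
    ## Trial 1: Anchor 94/200 (0.470), Reference 85/200 (0.425)
    trial1 = two_arm_trial("Trial 1",
                           make_arm("Anchor", 200L, 94L),
                           make_arm("Reference", 200L, 85L)),
    ## Trial 2: Anchor 183/350 (0.523), Placebo 64/350 (0.183)
    trial2 = two_arm_trial("Trial 2",
                           make_arm("Anchor", 350L, 183L),
                           make_arm("Placebo", 350L, 64L)),
    ## Trial 3: Anchor 53/100 (0.530), Placebo 5/50 (0.100)
    trial3 = two_arm_trial("Trial 3",
                           make_arm("Anchor", 100L, 53L),
                           make_arm("Placebo", 50L, 5L)))
}

#' Specify generative truths for a simulated two-arm trial
#'
#' @param rates Named vector of true response rates in (0, 1), one per arm;
#'   names are the arm labels.
#' @param n Named vector of per-arm sample sizes (same names as `rates`).
#' @return An object of class `true_trial_spec`.
#' @examples
#' true_trial_spec(c(Anchor = 0.470, Reference = 0.425),
#'                 c(Anchor = 200, Reference = 200))
#' @export
true_trial_spec <- function(rates, n) {
  if (!is.numeric(rates) || is.null(names(rates)) || any(!nzchar(names(rates))))
    am_stop_validation("rates must be a named numeric vector")
  if (!is.numeric(n) || is.null(names(n)))
    am_stop_validation("n must be a named numeric vector")
  if (length(rates) != 2L || length(n) != 2L)
    am_stop_validation("exactly two arms are required")
  if (!setequal(names(rates), names(n)))
    am_stop_validation("rates and n must name the same arms")
  if (anyDuplicated(names(rates)))
    am_stop_validation("arm labels must be distinct")
  if (any(rates <= 0 | rates >= 1))
    am_stop_validation("all true rates must lie strictly inside (0, 1)")
  if (any(n < 1 | n != as.integer(n)))
    am_stop_validation("all n must be positive integers")
  n <- n[names(rates)]
  structure(list(rates = rates, n = stats::setNames(as.integer(n), names(n))),
            class = "true_trial_spec")
}

#' Simulate a binomial two-arm trial
#'
#' Draws responder counts independently per arm as Binomial(n, rate) from a
#' [true_trial_spec()]. The seed is mandatory and fully determines the
#' result; no global random state is consumed implicitly.
#'
#' @param spec A [true_trial_spec()].
#' @param seed Integer seed (required).
#' @param trial_id Identifier for the simulated trial.
#' @return A [two_arm_trial()].
#' @examples
#' spec <- true_trial_spec(c(Anchor = 0.470, Reference = 0.425),
#'                         c(Anchor = 200, Reference = 200))
#' simulate_trial(spec, seed = 1)
#' @export
simulate_trial <- function(spec, seed, trial_id = "simulated") {
  if (!inherits(spec, "true_trial_spec"))
    am_stop_validation("spec must be a true_trial_spec")
  if (missing(seed) || is.null(seed) || !is.numeric(seed) || length(seed) != 1L)
    am_stop_validation("seed is required: supply a single integer seed")
  set.seed(as.integer(seed))
  x <- stats::rbinom(2L, size = spec$n, prob = spec$rates)
  two_arm_trial(trial_id,
                make_arm(names(spec$rates)[1], spec$n[[1]], x[1]),
                make_arm(names(spec$rates)[2], spec$n[[2]], x[2]))
}
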