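#' Sensitivity analysis 1: direct anchor-versus-placebo margin
#'
#' When the anchor drug has an effect similar to the reference drug, the
#' trial comparing Anchor to Placebo supports a classical direct margin
#' derivation. A direct margin not tighter than the indirect one backs the
#' consistency assumption of the indirect approach.
#'
#' @param anchor_placebo_trial A [two_arm_trial()] with anchor and placebo
#'   arms.
#' @param preservation Preservation fraction (default 0.60).
#' @param anchor_label,placebo_label Arm labels.
#' @param level Confidence level; `z` an optional critical value.
#' @param z Optional critical value; see [z_multiplier()].
#' @return An `equivalence_margin`.
#' @examples
#' sa1_direct_margin(case_study_trials()$trial2, 0.60)  # (0.724, 1.381)
#' @export
sa1_direct_margin <- function(anchor_placebo_trial, preservation = 0.60,
                              anchor_label = "Anchor",
                              placebo_label = "Placebo",
                              level = 0.95, z = NULL) {
  est <- trial_ratio(anchor_placebo_trial, anchor_label, placebo_label,
                     level = level, z = z)
  derive_margin(est, preservation)
}

## One point of the deterministic sweep: rebuild the Anchor-vs-Reference
## comparison at assumed rates, keep the Anchor-vs-Placebo estimate fixed,
## and evaluate the preservation the margin would achieve.
## mode "continuous": expected responder counts n*p enter the SE formula
## unrounded; mode "integer": responders are rounded to whole patients and
## the rates recomputed from the rounded counts.
sweep_eval <- function(reference_rate, anchor_rate, n_reference, n_anchor,
                       ap_est, margin_upper, zc, mode) {
  if (mode == "integer") {
    r_a <- round(n_anchor * anchor_rate)
    r_r <- round(n_reference * reference_rate)
    if (r_r < 1 || r_a < 1) return(NA_real_)
    log_ar <- log((r_a / n_anchor) / (r_r / n_reference))
  } else {
    r_a <- n_anchor * anchor_rate
    r_r <- n_reference * reference_rate
    log_ar <- log(anchor_rate / reference_rate)
  }
  se1 <- sqrt(1 / r_a + 1 / r_r - 1 / n_anchor - 1 / n_reference)
  log_ind <- ap_est$log_ratio - log_ar
  se <- sqrt(se1^2 + ap_est$se_log^2)
  ci_lower <- exp(log_ind - zc * se)
  if (ci_lower <= 1) return(NA_real_)
  c(ci_lower = ci_lower,
    preservation = 1 - log(margin_upper) / log(ci_lower))
}

default_reference_grid <- function(trial1, reference_label, level, z, by = 0.001) {
  ci <- wald_rate_ci(trial_arm(trial1, reference_label), level = level, z = z)
  seq(round(ci$lower, 3), round(ci$upper, 3), by = by)
}

#' Sensitivity analysis 2a: sweep the assumed reference response rate
#'
#' Holds the anchor response rate at its observed point estimate and varies
#' the assumed reference rate across a grid (by default the 95% Wald CI of
#' the observed reference rate, step 0.001, endpoints included). For each
#' candidate rate the Anchor-vs-Reference comparison is rebuilt at the
#' trial's per-arm sample sizes, the indirect lower CI bound against the
#' fixed Anchor-vs-Placebo trial recomputed, and the preservation achieved
#' by the supplied margin evaluated.
#'
#' @param trial1 The Anchor-vs-Reference [two_arm_trial()].
#' @param trial2 The Anchor-vs-Placebo [two_arm_trial()] (held fixed).
#' @param margin The proposed `equivalence_margin` to evaluate.
#' @param grid Candidate reference rates in (0, 1); `NULL` for the default.
#' @param mode `"continuous"` (expected responder counts, default) or
#'   `"integer"` (responders rounded to whole patients).
#' @param anchor_label,reference_label,placebo_label Arm labels.
#' @param level Confidence level; `z` an optional critical value.
#' @param z Optional critical value; see [z_multiplier()].
#' @return Data frame of sweep points: `reference_rate`, `anchor_rate`,
#'   `assumed_difference` (anchor minus reference), `indirect_ci_lower`,
#'   `preservation` (signed).
#' @export
sa2_sweep_reference <- function(trial1, trial2, margin, grid = NULL,
                                mode = c("continuous", "integer"),
                                anchor_label = "Anchor",
                                reference_label = "Reference",
                                placebo_label = "Placebo",
                                level = 0.95, z = NULL) {
  mode <- match.arg(mode)
  zc <- z_multiplier(level, z)
  if (!inherits(margin, "equivalence_margin"))
    am_stop_validation("margin must be an equivalence_margin")
  if (is.null(grid))
    grid <- default_reference_grid(trial1, reference_label, level, zc)
  if (any(grid <= 0 | grid >= 1))
    am_stop_validation("grid rates must lie strictly inside (0, 1)")
  anchor <- trial_arm(trial1, anchor_label)
  reference <- trial_arm(trial1, reference_label)
  ap_est <- trial_ratio(trial2, anchor_label, placebo_label,
                        level = level, z = zc)
  rows <- lapply(grid, function(p) {
    v <- sweep_eval(p, anchor$rate, reference$n, anchor$n,
                    ap_est, margin$upper, zc, mode)
    data.frame(reference_rate = p, anchor_rate = anchor$rate,
               assumed_difference = anchor$rate - p,
               indirect_ci_lower = if (all(is.na(v))) NA_real_ else v[["ci_lower"]],
               preservation = if (all(is.na(v))) NA_real_ else v[["preservation"]])
  })
  do.call(rbind, rows)
}

#' Sensitivity analysis 2b: sweep the anchor-minus-reference difference
#'
#' Varies both the assumed reference rate (over the grid of
#' [sa2_sweep_reference()]) and the assumed anchor-minus-reference rate
#' difference: for each pair the anchor rate is `reference + difference`.
#' Points with an anchor rate at or above 1 are skipped with a warning. Use
#' [min_preservation_by_difference()] to summarize the per-difference
#' worst case.
#'
#' @inheritParams sa2_sweep_reference
#' @param differences Anchor-minus-reference rate offsets; the case study
#'   uses `c(0.045, 0.060, 0.075, 0.090)` (observed, then up to twice
#'   observed).
#' @return Data frame of sweep points with an extra `difference` column.
#' @export
sa2_sweep_difference <- function(trial1, trial2, margin,
                                 differences = c(0.045, 0.060, 0.075, 0.090),
                                 grid = NULL,
                                 mode = c("continuous", "integer"),
                                 anchor_label = "Anchor",
                                 reference_label = "Reference",
                                 placebo_label = "Placebo",
                                 level = 0.95, z = NULL) {
  mode <- match.arg(mode)
  zc <- z_multiplier(level, z)
  if (!inherits(margin, "equivalence_margin"))
    am_stop_validation("margin must be an equivalence_margin")
  if (is.null(grid))
    grid <- default_reference_grid(trial1, reference_label, level, zc)
  anchor <- trial_arm(trial1, anchor_label)
  reference <- trial_arm(trial1, reference_label)
  ap_est <- trial_ratio(trial2, anchor_label, placebo_label,
                        level = level, z = zc)
  n_skipped <- 0L
  rows <- list()
  for (d in differences) {
    for (p in grid) {
      a <- p + d
      if (a >= 1) {
        n_skipped <- n_skipped + 1L
        next
      }
      v <- sweep_eval(p, a, reference$n, anchor$n, ap_est, margin$upper,
                      zc, mode)
      rows[[length(rows) + 1L]] <- data.frame(
        difference = d, reference_rate = p, anchor_rate = a,
        assumed_difference = d,
        indirect_ci_lower = if (all(is.na(v))) NA_real_ else v[["ci_lower"]],
        preservation = if (all(is.na(v))) NA_real_ else v[["preservation"]])
    }
  }
  if (n_skipped > 0L)
    warning(sprintf("%d sweep point(s) skipped: anchor rate >= 1", n_skipped))
  do.call(rbind, rows)
}

#' Minimum preservation per assumed difference
#'
#' @param sweep Output of [sa2_sweep_difference()].
#' @return Data frame with columns `difference`, `min_preservation`,
#'   `at_reference_rate`.
#' @export
min_preservation_by_difference <- function(sweep) {
  if (!is.data.frame(sweep) || is.null(sweep$difference))
    am_stop_validation("sweep must be the output of sa2_sweep_difference()")
  out <- lapply(split(sweep, sweep$difference), function(g) {
    i <- which.min(g$preservation)
    data.frame(difference = g$difference[1],
               min_preservation = g$preservation[i],
               at_reference_rate = g$reference_rate[i])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$difference), , drop = FALSE]
}

prior_shape <- function(prior) {
  switch(match.arg(prior, c("uniform", "jeffreys")),
         uniform = c(1, 1),
         jeffreys = c(0.5, 0.5))
}

new_simulation_result <- function(draws, n_excluded, n_reps, seed, prior,
                                  margin_upper, simulated_arms) {
  structure(list(preservation_draws = draws,
                 n_valid = length(draws),
                 n_excluded = n_excluded,
                 n_reps = n_reps, seed = seed, prior = prior,
                 margin_upper = margin_upper,
                 simulated_arms = simulated_arms),
            class = "simulation_result")
}

## Core posterior-predictive simulation. Per replicate: the true rate of
## each simulated arm is drawn from its Beta posterior (prior + observed
## counts), a new responder count is drawn Binomial(n, rate*), and the
## indirect lower CI bound and achieved preservation are recomputed with
## the remaining arms fixed at their observed counts. Replicates whose
## simulated counts make the log-ratio SE or the preservation undefined
## (zero responders, indirect bound <= 1) are excluded and counted.
simulate_preservation <- function(trial1, trial2, margin, n_reps, seed,
                                  prior, simulate_anchor,
                                  anchor_label, reference_label,
                                  placebo_label, level, z) {
  if (!inherits(margin, "equivalence_margin"))
    am_stop_validation("margin must be an equivalence_margin")
  if (!is.numeric(n_reps) || length(n_reps) != 1L || n_reps < 1)
    am_stop_validation("n_reps must be a positive integer")
  if (missing(seed) || is.null(seed) || !is.numeric(seed) || length(seed) != 1L)
    am_stop_validation("seed is required: supply a single integer seed")
  zc <- z_multiplier(level, z)
  shape <- prior_shape(prior)
  anchor <- trial_arm(trial1, anchor_label)
  reference <- trial_arm(trial1, reference_label)
  ap_est <- trial_ratio(trial2, anchor_label, placebo_label,
                        level = level, z = zc)
  n_reps <- as.integer(n_reps)

  set.seed(as.integer(seed))
  mu_r <- stats::rbeta(n_reps, shape[1] + reference$responders,
                       shape[2] + reference$n - reference$responders)
  x_r <- stats::rbinom(n_reps, reference$n, mu_r)
  if (simulate_anchor) {
    mu_a <- stats::rbeta(n_reps, shape[1] + anchor$responders,
                         shape[2] + anchor$n - anchor$responders)
    x_a <- stats::rbinom(n_reps, anchor$n, mu_a)
  } else {
    x_a <- rep.int(anchor$responders, n_reps)
  }

  valid <- x_r >= 1L & x_a >= 1L
  log_ar <- log((x_a / anchor$n) / (x_r / reference$n))
  se1sq <- 1 / x_a + 1 / x_r - 1 / anchor$n - 1 / reference$n
  ci_lower <- exp(ap_est$log_ratio - log_ar -
                    zc * sqrt(se1sq + ap_est$se_log^2))
  valid <- valid & ci_lower > 1
  draws <- 1 - log(margin$upper) / log(ci_lower[valid])
  new_simulation_result(draws, n_excluded = sum(!valid),
                        n_reps = n_reps, seed = as.integer(seed),
                        prior = match.arg(prior, c("uniform", "jeffreys")),
                        margin_upper = margin$upper,
                        simulated_arms = if (simulate_anchor)
                          c(reference_label, anchor_label) else reference_label)
}

#' Sensitivity analysis 2c: posterior-predictive simulation of the reference arm
#'
#' Quantifies how likely a given preservation target is under uncertainty in
#' the reference response rate. Per replicate, a true reference rate is
#' drawn from the Beta posterior of the observed reference arm (uniform
#' Beta(1,1) prior by default), a new responder count is drawn
#' Binomial(n, rate), and the achieved preservation of the supplied margin
#' is recomputed with the anchor arm and the Anchor-vs-Placebo trial fixed
#' at their observed data.
#'
#' @inheritParams sa2_sweep_reference
#' @param n_reps Number of replicates.
#' @param seed Integer seed (required; no implicit global randomness).
#' @param prior `"uniform"` (Beta(1,1), default) or `"jeffreys"`
#'   (Beta(0.5,0.5)).
#' @return A `simulation_result` with the valid `preservation_draws`, the
#'   count of excluded (undefined) replicates, and metadata. Use
#'   [exceedance()] for tail probabilities.
#' @examples
#' tr <- case_study_trials()
#' m <- derive_margin(indirect_ratio(
#'   trial_ratio(tr$trial1, "Anchor", "Reference"),
#'   trial_ratio(tr$trial2, "Anchor", "Placebo")), 0.60)
#' sim <- sa2_simulate_reference(tr$trial1, tr$trial2, m,
#'                               n_reps = 1000, seed = 42)
#' exceedance(sim, c(0.5, 0.6))
#' @export
sa2_simulate_reference <- function(trial1, trial2, margin, n_reps = 1000,
                                   seed, prior = "uniform",
                                   anchor_label = "Anchor",
                                   reference_label = "Reference",
                                   placebo_label = "Placebo",
                                   level = 0.95, z = NULL) {
  simulate_preservation(trial1, trial2, margin, n_reps, seed, prior,
                        simulate_anchor = FALSE,
                        anchor_label, reference_label, placebo_label,
                        level, z)
}

#' Sensitivity analysis 2d: posterior-predictive simulation of both arms
#'
#' As [sa2_simulate_reference()], but the anchor arm's response rate and
#' responder count are also redrawn from their own (independent) posterior,
#' reflecting uncertainty in both the reference effect and the
#' anchor-versus-reference difference.
#'
#' @inheritParams sa2_simulate_reference
#' @return A `simulation_result`.
#' @export
sa2_simulate_both <- function(trial1, trial2, margin, n_reps = 1000,
                              seed, prior = "uniform",
                              anchor_label = "Anchor",
                              reference_label = "Reference",
                              placebo_label = "Placebo",
                              level = 0.95, z = NULL) {
  simulate_preservation(trial1, trial2, margin, n_reps, seed, prior,
                        simulate_anchor = TRUE,
                        anchor_label, reference_label, placebo_label,
                        level, z)
}

#' Probability of retaining at least a target fraction of the effect
#'
#' The proportion of replicates whose achieved preservation is greater than
#' or equal to the target. Replicates that hit the target exactly count as
#' successes; because the replicate reproducing the observed counts achieves
#' the margin's own preservation factor exactly (a boundary that carries
#' several percent of the predictive mass), the comparison is shielded from
#' floating-point round-off by a tiny tolerance.
#'
#' @param sim A `simulation_result`.
#' @param f Target preservation fraction(s).
#' @param tol Numerical tolerance for the boundary comparison (default
#'   `1e-9`; set 0 for a raw `>=`).
#' @return For each `f`, the proportion of valid replicates with achieved
#'   preservation `>= f`.
#' @export
exceedance <- function(sim, f, tol = 1e-9) {
  if (!inherits(sim, "simulation_result"))
    am_stop_validation("sim must be a simulation_result")
  vapply(f, function(t) mean(sim$preservation_draws >= t - tol), numeric(1))
}

#' Exceedance curve over a grid of targets
#'
#' @param sim A `simulation_result`.
#' @param f Grid of target fractions (default 0 to 1 by 0.01).
#' @param tol Boundary tolerance passed to [exceedance()].
#' @return Data frame with columns `f_target` and `probability`
#'   (monotonically non-increasing in `f_target`).
#' @export
exceedance_curve <- function(sim, f = seq(0, 1, by = 0.01), tol = 1e-9) {
  data.frame(f_target = f, probability = exceedance(sim, f, tol = tol))
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf(
    "Posterior-predictive simulation (%s arm%s), %d replicates, seed %d, %s prior\n",
    paste(x$simulated_arms, collapse = " + "),
    if (length(x$simulated_arms) > 1) "s" else "", x$n_reps, x$seed, x$prior))
  if (x$n_excluded > 0)
    cat(sprintf("  %d replicate(s) excluded (undefined preservation)\n",
                x$n_excluded))
  cat(sprintf("  P(f >= 0.5) = %.3f, P(f >= 0.6) = %.3f (margin upper %.3f)\n",
              exceedance(x, 0.5), exceedance(x, 0.6), x$margin_upper))
  invisible(x)
}

#' Sensitivity analysis 3: pooling heterogeneous trials before the indirect step
#'
#' Includes additional Anchor-vs-Placebo trials (possibly with somewhat
#' different populations) by random-effects pooling of their rate ratios
#' before the anchor-based indirect comparison, then re-derives the margin.
#' Optionally reports the preservation that a previously proposed margin
#' still achieves against the pooled indirect estimate.
#'
#' @param trial1 The Anchor-vs-Reference [two_arm_trial()].
#' @param anchor_placebo_trials List of Anchor-vs-Placebo
#'   [two_arm_trial()] objects (a single trial reduces exactly to the base
#'   analysis).
#' @param preservation Preservation fraction for the re-derived margin.
#' @param legacy_margin Optional `equivalence_margin` (or numeric upper
#'   bound) whose achieved preservation against the pooled indirect
#'   estimate is reported.
#' @param anchor_label,reference_label,placebo_label Arm labels.
#' @param level Confidence level; `z` an optional critical value.
#' @param z Optional critical value; see [z_multiplier()].
#' @return An object of class `sa3_result`: list with `pooled` (the
#'   Anchor-vs-Placebo `meta_result` or single-trial estimate), `indirect`
#'   (Reference-vs-Placebo `ratio_estimate`), `margin`
#'   (`equivalence_margin`) and `legacy_preservation` (or `NA`).
#' @examples
#' tr <- case_study_trials()
#' sa3_pooled_indirect(tr$trial1, list(tr$trial2, tr$trial3),
#'                     preservation = 0.60, legacy_margin = 1.283)
#' @export
sa3_pooled_indirect <- function(trial1, anchor_placebo_trials,
                                preservation = 0.60, legacy_margin = NULL,
                                anchor_label = "Anchor",
                                reference_label = "Reference",
                                placebo_label = "Placebo",
                                level = 0.95, z = NULL) {
  if (!is.list(anchor_placebo_trials) || length(anchor_placebo_trials) < 1L)
    am_stop_validation("anchor_placebo_trials must be a non-empty list of trials")
  ests <- lapply(anchor_placebo_trials, trial_ratio,
                 numerator_label = anchor_label,
                 denominator_label = placebo_label,
                 level = level, z = z)
  pooled <- if (length(ests) == 1L) ests[[1]]
            else pool_random_dl(ests, level = level, z = z)
  avr <- trial_ratio(trial1, anchor_label, reference_label,
                     level = level, z = z)
  ind <- indirect_ratio(avr, pooled, level = level, z = z)
  margin <- derive_margin(ind, preservation)
  legacy <- NA_real_
  if (!is.null(legacy_margin))
    legacy <- preservation_of(legacy_margin, ind$ci_lower)
  structure(list(pooled = pooled, indirect = ind, margin = margin,
                 legacy_preservation = legacy),
            class = "sa3_result")
}

#' @export
print.sa3_result <- function(x, ...) {
  print(x$pooled)
  print(x$indirect)
  print(x$margin)
  if (!is.na(x$legacy_preservation))
    cat(sprintf("Legacy margin preserves %.1f%% of the pooled indirect effect\n",
                100 * x$legacy_preservation))
  invisible(x)
}
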