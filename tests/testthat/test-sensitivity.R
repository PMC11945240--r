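tr <- case_study_trials()
margin60 <- fixture_margin(0.60)

test_that("the direct anchor-vs-placebo margin matches the published values", {
  m <- sa1_direct_margin(tr$trial2, 0.60)
  expect_equal(round(c(m$lower, m$upper), 3), c(0.724, 1.381))
  # degenerate preservations
  m1 <- sa1_direct_margin(tr$trial2, 1)
  expect_equal(c(m1$lower, m1$upper), c(1, 1))
  m0 <- sa1_direct_margin(tr$trial2, 0)
  direct <- trial_ratio(tr$trial2, "Anchor", "Placebo")
  expect_equal(m0$upper, direct$ci_lower)
  expect_equal(m0$lower, 1 / direct$ci_lower)
})

test_that("the reference-rate sweep covers the CI grid and recovers known points", {
  sw <- sa2_sweep_reference(tr$trial1, tr$trial2, margin60)
  expect_equal(nrow(sw), 139L)
  expect_equal(range(sw$reference_rate), c(0.356, 0.494))
  # at the observed rate the round trip is forced to the design preservation
  at_obs <- sw$preservation[abs(sw$reference_rate - 0.425) < 1e-9]
  expect_equal(at_obs, 0.60, tolerance = 1e-10)
  # a reference rate as low as 38.0% still preserves at least half the effect
  at_380 <- sw$preservation[abs(sw$reference_rate - 0.380) < 1e-9]
  expect_gte(at_380, 0.50)
  # monotone: larger assumed reference rate preserves more
  expect_true(all(diff(sw$preservation) > 0))
})

test_that("the difference sweep reproduces the published worst-case preservations", {
  sw <- sa2_sweep_difference(tr$trial1, tr$trial2, margin60)
  mins <- min_preservation_by_difference(sw)
  expect_equal(mins$difference, c(0.045, 0.060, 0.075, 0.090))
  expect_lt(max(abs(100 * mins$min_preservation - c(57.1, 54.4, 51.4, 48.2))),
            0.15)  # +/- 0.15 percentage points
  # every per-difference minimum sits at the lower grid endpoint
  expect_true(all(mins$at_reference_rate == 0.356))
  # integer-rounded responder counts are an accepted alternative convention
  swi <- sa2_sweep_difference(tr$trial1, tr$trial2, margin60, mode = "integer")
  mins_i <- min_preservation_by_difference(swi)
  expect_equal(100 * mins_i$min_preservation[4], 48.2, tolerance = 0.05)
  # a zero difference with reference at the anchor rate gives the
  # anchor-vs-placebo effect back (trial-1 ratio becomes 1)
  sw0 <- sa2_sweep_difference(tr$trial1, tr$trial2, margin60,
                              differences = 0, grid = 0.470)
  avp <- trial_ratio(tr$trial2, "Anchor", "Placebo")
  se_ind <- sqrt(1 / 94 + 1 / 94 - 2 / 200 + avp$se_log^2)
  expect_equal(sw0$indirect_ci_lower, exp(avp$log_ratio - 1.96 * se_ind))
})

test_that("sweep inputs are validated and unreachable points skipped", {
  expect_error(sa2_sweep_reference(tr$trial1, tr$trial2, margin60, grid = 0),
               "grid")
  expect_warning(
    sa2_sweep_difference(tr$trial1, tr$trial2, margin60,
                         differences = 0.7, grid = c(0.4, 0.45)),
    "skipped")
})

test_that("posterior-predictive simulations are seed-deterministic", {
  s1 <- sa2_simulate_reference(tr$trial1, tr$trial2, margin60,
                               n_reps = 500, seed = 7)
  s2 <- sa2_simulate_reference(tr$trial1, tr$trial2, margin60,
                               n_reps = 500, seed = 7)
  expect_identical(s1$preservation_draws, s2$preservation_draws)
  s3 <- sa2_simulate_reference(tr$trial1, tr$trial2, margin60,
                               n_reps = 500, seed = 8)
  expect_false(identical(s1$preservation_draws, s3$preservation_draws))
  expect_error(sa2_simulate_reference(tr$trial1, tr$trial2, margin60,
                                      n_reps = 10),
               "seed")
})

test_that("exceedance curves are exact proportions and monotone non-increasing", {
  sim <- sa2_simulate_both(tr$trial1, tr$trial2, margin60,
                           n_reps = 2000, seed = 42)
  curve <- exceedance_curve(sim)
  expect_true(all(diff(curve$probability) <= 0))
  f <- 0.55
  expect_equal(exceedance(sim, f, tol = 0),
               sum(sim$preservation_draws >= f) / sim$n_valid)
  # single replicate: a step function in {0, 1}
  one <- sa2_simulate_reference(tr$trial1, tr$trial2, margin60,
                                n_reps = 1, seed = 3)
  expect_true(all(exceedance_curve(one)$probability %in% c(0, 1)))
})

test_that("simulated exceedance sits in the calibrated band around one half", {
  sim <- sa2_simulate_reference(tr$trial1, tr$trial2, margin60,
                                n_reps = 20000, seed = 20)
  p60 <- exceedance(sim, 0.60)
  expect_gte(p60, 0.48)
  expect_lte(p60, 0.54)
  p50 <- exceedance(sim, 0.50)
  expect_gte(p50, 0.79)
  expect_lte(p50, 0.87)
  # an undefined replicate (indirect bound at or below 1) is a rare but
  # possible draw; it must be excluded and counted, never silently kept
  expect_lte(sim$n_excluded, 5L)
  expect_identical(sim$n_valid + sim$n_excluded, sim$n_reps)
})

test_that("with huge arms the simulation concentrates at the design preservation", {
  big1 <- two_arm_trial("big", make_arm("Anchor", 2000000, 940000),
                        make_arm("Reference", 2000000, 850000))
  ind <- indirect_ratio(trial_ratio(big1, "Anchor", "Reference"),
                        trial_ratio(tr$trial2, "Anchor", "Placebo"))
  m <- derive_margin(ind, 0.60)
  sim <- sa2_simulate_both(big1, tr$trial2, m, n_reps = 400, seed = 5)
  expect_lt(diff(range(sim$preservation_draws)), 0.01)
  expect_equal(median(sim$preservation_draws), 0.60, tolerance = 5e-3)
})

test_that("pooling heterogeneous trials before the indirect step matches the published SA3", {
  res <- sa3_pooled_indirect(tr$trial1, list(tr$trial2, tr$trial3),
                             preservation = 0.60, legacy_margin = 1.283)
  expect_equal(round(res$pooled$ratio, 3), 3.382)
  expect_equal(round(res$indirect$ratio, 3), 3.059)
  expect_equal(round(c(res$margin$lower, res$margin$upper), 3),
               c(0.807, 1.240))
  expect_equal(res$legacy_preservation, 0.536, tolerance = 5e-4)
  # a single anchor-placebo trial reduces exactly to the base analysis
  res1 <- sa3_pooled_indirect(tr$trial1, list(tr$trial2), preservation = 0.60)
  base <- indirect_ratio(trial_ratio(tr$trial1, "Anchor", "Reference"),
                         trial_ratio(tr$trial2, "Anchor", "Placebo"))
  expect_equal(res1$indirect$log_ratio, base$log_ratio)
  expect_equal(res1$indirect$se_log, base$se_log)
  expect_equal(res1$margin$upper, margin60$upper)
})
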