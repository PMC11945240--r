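tr <- case_study_trials()
ap_estimates <- function() list(trial_ratio(tr$trial2, "Anchor", "Placebo"),
                                trial_ratio(tr$trial3, "Anchor", "Placebo"))

test_that("common-effect inverse-variance pooling matches a hand summation", {
  ests <- ap_estimates()
  fe <- pool_common_iv(ests)
  w <- 1 / c(ests[[1]]$se_log, ests[[2]]$se_log)^2
  theta <- c(ests[[1]]$log_ratio, ests[[2]]$log_ratio)
  expect_equal(fe$log_ratio, sum(w * theta) / sum(w))
  expect_equal(fe$se_log, sqrt(1 / sum(w)))
  expect_equal(sum(fe$weights), 1)
  # single estimate: identity
  one <- pool_common_iv(ests[1])
  expect_equal(one$log_ratio, ests[[1]]$log_ratio)
  expect_equal(one$se_log, ests[[1]]$se_log)
  # two equal estimates: same point, se / sqrt(2)
  twin <- pool_common_iv(list(ests[[1]], ests[[1]]))
  expect_equal(twin$log_ratio, ests[[1]]$log_ratio)
  expect_equal(twin$se_log, ests[[1]]$se_log / sqrt(2))
})

test_that("random-effects pooling reproduces the published combined-trials row", {
  re <- pool_random_dl(ap_estimates())
  expect_equal(round(re$ratio, 3), 3.382)
  expect_equal(round(re$se_log, 3), 0.275)
  expect_equal(round(c(re$ci_lower, re$ci_upper), 3), c(1.974, 5.795))
  expect_gt(re$tau2, 0)
  expect_equal(re$tau2, 0.0883, tolerance = 1e-3)
  expect_equal(sum(re$weights), 1)
})

test_that("DL estimates agree with the explicit-summation oracle and metafor", {
  ests <- ap_estimates()
  theta <- vapply(ests, `[[`, numeric(1), "log_ratio")
  se <- vapply(ests, `[[`, numeric(1), "se_log")
  orc <- oracle_dl(theta, se)
  re <- pool_random_dl(ests)
  expect_equal(re$log_ratio, orc$pooled)
  expect_equal(re$se_log, orc$se)
  expect_equal(re$q_stat, orc$q)
  expect_equal(re$tau2, orc$tau2)
  # independent implementation: metafor with DL and equal-effects models
  fit_dl <- metafor::rma(yi = theta, vi = se^2, method = "DL")
  expect_equal(re$log_ratio, as.numeric(fit_dl$beta), tolerance = 1e-10)
  expect_equal(re$se_log, fit_dl$se, tolerance = 1e-10)
  expect_equal(re$tau2, fit_dl$tau2, tolerance = 1e-10)
  fit_ee <- metafor::rma(yi = theta, vi = se^2, method = "EE")
  fe <- pool_common_iv(ests)
  expect_equal(fe$log_ratio, as.numeric(fit_ee$beta), tolerance = 1e-10)
  expect_equal(fe$se_log, fit_ee$se, tolerance = 1e-10)
})

test_that("random-effects pooling is never more precise than common-effect", {
  set.seed(21)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    theta <- rnorm(k, 0.8, 0.5)
    se <- runif(k, 0.05, 0.5)
    ests <- lapply(seq_len(k), function(j) {
      e <- trial_ratio(tr$trial2, "Anchor", "Placebo")
      e$log_ratio <- theta[j]; e$ratio <- exp(theta[j]); e$se_log <- se[j]
      e
    })
    fe <- pool_common_iv(ests)
    re <- pool_random_dl(ests)
    expect_gte(re$se_log, fe$se_log)
    # order invariance
    perm <- sample(k)
    expect_equal(pool_random_dl(ests[perm])$log_ratio, re$log_ratio)
    expect_equal(pool_random_dl(ests[perm])$tau2, re$tau2)
    # tau2 == 0 implies the random-effects result equals the common one
    if (re$tau2 == 0) {
      expect_equal(re$log_ratio, fe$log_ratio)
      expect_equal(re$se_log, fe$se_log)
    }
  }
})

test_that("homogeneous studies give tau2 = 0 and the common-effect answer", {
  e <- trial_ratio(tr$trial2, "Anchor", "Placebo")
  re <- pool_random_dl(list(e, e, e))
  fe <- pool_common_iv(list(e, e, e))
  expect_equal(re$tau2, 0)
  expect_equal(re$q_stat, 0)
  expect_equal(re$log_ratio, fe$log_ratio)
  expect_equal(re$se_log, fe$se_log)
})

test_that("with large heterogeneity RE weights approach equality", {
  e1 <- trial_ratio(tr$trial2, "Anchor", "Placebo")
  e2 <- trial_ratio(tr$trial3, "Anchor", "Placebo")
  # inflate heterogeneity by pushing the log ratios far apart
  e1$log_ratio <- 0; e2$log_ratio <- 30
  re <- pool_random_dl(list(e1, e2))
  expect_equal(as.numeric(re$weights), c(0.5, 0.5), tolerance = 1e-3)
  expect_equal(re$log_ratio, mean(c(0, 30)), tolerance = 1e-2)
})

test_that("Mantel-Haenszel pooling matches the cell-sum oracle and needs counts", {
  mh <- pool_common_mh(list(tr$trial2, tr$trial3), "Anchor", "Placebo")
  expect_equal(mh$ratio, oracle_mh_rr(a = c(183, 53), n1 = c(350, 100),
                                      c = c(64, 5), n2 = c(350, 50)))
  # the MH common-effect ratio is not the random-effects 3.382
  expect_false(isTRUE(all.equal(round(mh$ratio, 3), 3.382)))
  expect_equal(sum(mh$weights), 1)
  # single trial reduces to the direct ratio
  one <- pool_common_mh(list(tr$trial2), "Anchor", "Placebo")
  direct <- trial_ratio(tr$trial2, "Anchor", "Placebo")
  expect_equal(one$ratio, direct$ratio, tolerance = 1e-10)
  expect_equal(one$se_log, direct$se_log, tolerance = 1e-10)
  # replicated identical tables keep the same ratio
  twin <- pool_common_mh(list(tr$trial2, tr$trial2), "Anchor", "Placebo")
  expect_equal(twin$ratio, direct$ratio, tolerance = 1e-10)
  # summary-only input is rejected with an explanation
  expect_error(pool_common_mh(ap_estimates(), "Anchor", "Placebo"),
               "2x2 counts")
})

test_that("pooling validates its inputs", {
  expect_error(pool_common_iv(list()), "non-empty")
  mixed <- list(trial_ratio(tr$trial2, "Anchor", "Placebo"),
                trial_ratio(tr$trial1, "Anchor", "Reference"))
  expect_error(pool_common_iv(mixed), "same arms")
})

test_that("forest data reproduces per-study estimates and pooled rows", {
  fd <- forest_data(ap_estimates())
  expect_equal(nrow(fd), 4L)
  direct2 <- trial_ratio(tr$trial2, "Anchor", "Placebo")
  expect_equal(fd$ratio[1], direct2$ratio)
  expect_equal(fd$ci_lower[1], direct2$ci_lower)
  expect_equal(fd$ratio[4], pool_random_dl(ap_estimates())$ratio)
  expect_equal(sum(fd$weight_common[1:2]), 1)
  expect_equal(sum(fd$weight_random[1:2]), 1)
})
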