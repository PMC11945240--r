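## Independent brute-force oracles used to cross-check the implementation.

## Delta-method SE of the log rate ratio by explicit summation of the four
## reciprocal terms (kept deliberately separate from the package's code path).
oracle_se_log <- function(r1, n1, r2, n2) {
  terms <- c(1 / r1, 1 / r2, -1 / n1, -1 / n2)
  s <- 0
  for (t in terms) s <- s + t
  sqrt(s)
}

## DerSimonian-Laird by explicit summation over studies.
oracle_dl <- function(log_ratios, se_logs) {
  w <- 1 / se_logs^2
  fixed <- sum(w * log_ratios) / sum(w)
  q <- sum(w * (log_ratios - fixed)^2)
  cval <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (q - (length(w) - 1)) / cval)
  wstar <- 1 / (se_logs^2 + tau2)
  list(pooled = sum(wstar * log_ratios) / sum(wstar),
       se = sqrt(1 / sum(wstar)), q = q, tau2 = tau2)
}

## Mantel-Haenszel pooled risk ratio by explicit cell sums.
oracle_mh_rr <- function(a, n1, c, n2) {
  N <- n1 + n2
  sum(a * n2 / N) / sum(c * n1 / N)
}

## A tiny deterministic margin oracle evaluated directly from the formula.
oracle_margin_upper <- function(bound, f) exp(log(bound) * (1 - f))

fixture_trials <- function() case_study_trials()

fixture_margin <- function(preservation = 0.60) {
  tr <- fixture_trials()
  ind <- indirect_ratio(trial_ratio(tr$trial1, "Anchor", "Reference"),
                        trial_ratio(tr$trial2, "Anchor", "Placebo"))
  derive_margin(ind, preservation)
}
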