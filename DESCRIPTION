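Package: anchormargin
Title: Equivalence Margin Derivation by Anchor-Based Indirect Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Derives equivalence margins for biosimilar efficacy trials when no
    historical head-to-head Reference-versus-Placebo trial exists. Implements
    direct within-trial response-rate-ratio estimation, the anchor-based
    indirect comparison (log-scale effect difference with summed variances),
    95-95 fixed-margin derivation with a stated preservation factor and its
    inversion, equivalence verdicts for a future trial's confidence interval,
    common-effect (inverse-variance and Mantel-Haenszel) and
    DerSimonian-Laird random-effects pooling with heterogeneity statistics,
    and three sensitivity analyses: a direct anchor-versus-placebo margin,
    deterministic sweeps and posterior-predictive Monte-Carlo simulation over
    assumed response rates, and pooling of heterogeneous trials before the
    indirect step. Includes a binomial trial simulator, the worked case-study
    fixture, CSV/JSON trial input-output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    optparse,
    metafor
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
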