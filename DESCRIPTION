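Package: adipomr
Title: Mendelian Randomization Pipeline for Adiposity and Mental Health
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A causal-inference toolkit for studying the effect of adiposity
    on mental health and well-being outcomes with genetic instruments.
    Implements covariate-adjusted observational regressions, one-sample
    two-stage least-squares Mendelian randomization on individual-level
    data, two-sample summary-statistic Mendelian randomization (Wald
    ratios, multiplicative random-effects inverse-variance weighting,
    MR-Egger, weighted and penalized weighted median, Cochran's Q), and
    stratified non-linear Mendelian randomization (IV-free exposure,
    decile-wise local average causal effects, a continuity-constrained
    piecewise-linear causal curve with bootstrap bands, and heterogeneity
    and quadratic non-linearity tests). A synthetic-cohort simulator with
    known generative truth makes every estimator verifiable by parameter
    recovery, standing in for restricted biobank individual-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    metafor,
    vcfR
Config/testthat/edition: 3
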