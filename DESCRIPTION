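Package: grsmr
Title: Genetic Risk Score Mendelian Randomisation with Simulated Cohorts
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end Mendelian randomisation (MR) toolkit for binary
    disease outcomes: phenotype derivation and case labelling from ICD-style
    diagnosis records, allele-harmonised additive genetic risk scores with
    instrument-strength diagnostics, two-stage one-sample MR with bootstrap
    confidence intervals and exclusion-restriction testing, stratified
    estimates with Cochran's Q heterogeneity, summary-data two-sample MR
    (inverse-variance weighted with multiplicative random effects, MR-Egger,
    multivariable MR), sliding-window non-linear MR, and a stepwise
    confounder-attenuation search. Includes a synthetic-cohort generator with
    known causal structure (confounding, pleiotropy, effect modification) so
    every estimator can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    withr
Config/testthat/edition: 3
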