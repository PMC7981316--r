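Package: igmnet
Title: Neural-Net Subgroup Discovery Linking Immunoglobulin M to
    Psychopathology in Polypharmacy Cohorts
Version: 0.1.0
Authors@R:
    person("Response-Genetics", "Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantitative psychopathology analysis in naturalistic
    inpatient cohorts under polypharmacy: a seeded synthetic cohort generator
    with a planted IgM-linked patient subgroup, scoring and classification
    rules for standard instruments (HAM-D, PANSS, MEDIS, syndrome check
    lists), pairwise syndrome-profile concordance, a multi-layer sigmoid
    backpropagation network written from first principles with 10-fold
    cross-validation, a constrained search for the largest patient subgroup
    whose serum IgM levels track global psychopathology scores at a minimal
    false-positive response-prediction rate, and variance-decomposition
    analyses of polypharmacy and drug-count-driven side effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
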