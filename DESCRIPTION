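Package: paincpm
Title: Connectome-Based Predictive Modelling of Pain-Related Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and externally validating sparse linear
    predictive models of pain-related associative learning from resting-state
    functional connectomes. Computes differential valence-change learning
    scores from conditioning ratings, partial-correlation connectivity
    matrices from region timeseries (with Ledoit-Wolf covariance shrinkage),
    trains ridge-regression models with k-best edge selection under nested
    leave-one-participant-out cross-validation, assesses significance by
    permutation, applies frozen models to external cohorts without refitting,
    tests validators and confounders with a conditional-permutation
    independence test, and quantifies edge and region importance by
    exclusion loss. Includes a synthetic-cohort generator with known ground
    truth so the whole pipeline can be exercised and calibrated without any
    imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
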