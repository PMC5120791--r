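Package: flowforest
Title: Random-Forest Surrogates for Cerebral Blood Flow from Transcranial Doppler
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for testing whether transcranial Doppler blood flow velocity,
    together with easily available clinical covariates, predicts cerebral blood
    flow as measured by arterial spin labeling perfusion MRI. Provides a
    from-scratch CART regression-forest implementation with bootstrap
    aggregation, iterative random-forest imputation of mixed-type clinical
    tables, a Poiseuille-flow TCD estimator of cerebral blood flow with
    diameter-error propagation, a synthetic patient-cohort generator matching
    published cohort summary statistics, and four grouped leave-out
    cross-validation designs (leave-one-measurement, leave-one-side,
    leave-one-visit, leave-one-patient) with correlation reporting.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    randomForest
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
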