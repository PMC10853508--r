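Package: nirsmvpa
Title: Multivariate Pattern Classification of fNIRS Hemodynamic Responses
    with Nested Cross-Validation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for decoding group membership and clinical severity from
    channel-space functional near-infrared spectroscopy (fNIRS) activation
    maps. Implements a complete small-sample decoding pipeline: canonical
    double-gamma HRF regressors and GLM beta estimation from two-chromophore
    (HbO/HbR) time series, cosine-basis drift removal and spatial
    global-component filtering, across-subject principal component
    decomposition of beta maps, t-score feature ranking, univariate
    threshold and linear support-vector-machine classification under
    leave-one-out cross-validation with either fold-internal (nested) or
    pooled (leaky) feature selection, permutation null distributions with
    significance thresholds, and prediction of symptom-severity scores from
    continuous SVM decision values. A synthetic-cohort generator with known
    ground truth supports calibration and recovery studies, in particular
    quantification of the accuracy inflation caused by feature-selection
    leakage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    Rcpp,
    jsonlite,
    S4Vectors,
    SummarizedExperiment,
    arrow
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse
Config/testthat/edition: 3
biocViews: Classification, DimensionReduction, Regression, Software
RoxygenNote: 7.3.3
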