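Package: credscan
Title: Single-Trial EEG Message-Credibility Classification via Time-Window
    and Brain-Region Model Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Pipeline for predicting message-credibility decisions from
    source-space EEG currents. Generates synthetic cohorts of per-trial
    region-by-time cortical current matrices with planted class effects,
    computes mean electric charge (MEC) per region per 5 ms bin and its
    per-participant min-max normalisation (sMEC), performs an exhaustive
    search over post-stimulus time windows and small brain-region subsets
    with bootstrap-validated logistic classifiers, evaluates selected
    models on held-out participants, and reproduces the accompanying
    behavioral credibility-bias statistics. Includes a standardized
    minimum-norm (sLORETA-style) inverse solution on toy lead fields so
    the pipeline can start from synthetic scalp potentials.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    MASS,
    arrow
Config/testthat/edition: 3
RoxygenNote: 7.3.3
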