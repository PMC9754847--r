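Package: seizconn
Title: Seizure Prediction from Dynamic EEG Functional Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Two-stage, interpretable seizure prediction from scalp EEG.
    Stage one estimates, for every nonoverlapping 60-second epoch, a dynamic
    brain functional connectivity network: kernel-weighted time-varying
    covariance matrices are averaged within the epoch and inverted under an
    L1 penalty (graphical lasso), and the resulting sparse precision matrix
    is rescaled to partial correlations whose vectorized upper triangle
    forms a network predictor. Stage two classifies preictal versus
    interictal epochs with a bootstrap-ensembled lasso-penalized logistic
    regression, reporting per-edge selection frequencies as importance
    weights alongside sensitivity, false discovery rate and AUC. Includes a
    matrix-normal simulator with planted class-differential precision
    structure, EDF input, seizure-annotation handling, state labeling and
    epoching, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
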