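Package: focis
Title: Feature-Optimized Classification of Independent Components with SVM
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Automated binary classification of independent component analysis
    (ICA) results from resting-state fMRI into resting-state functional
    networks (RFN) and artifacts (ART). Implements the FOCIS approach:
    five spatial and temporal features computed from thresholded component
    statistic maps and their time courses, F-score driven feature selection
    with a binomial-GLM explanatory-power test, a boundary-constrained
    RBF-kernel support vector machine with asymmetric class costs and
    exhaustive hyper-parameter grid search, epsilon-SVR tracking of a
    component across ICA model orders with the CISOTA change index, and
    Monte-Carlo calibration of cluster-extent thresholds. A seeded synthetic
    IC generator emulates melodic-style outputs so the whole pipeline is
    testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    kernlab,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
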