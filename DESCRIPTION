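Package: octguide
Title: Computer-Aided Epidural Needle Guidance from Forward-View OCT B-Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for computer-aided guidance of epidural needle placement
    from forward-view optical coherence tomography (OCT) B-scans. Provides a
    synthetic B-scan generator for the five epidural tissue layers (fat,
    interspinous ligament, ligamentum flavum, epidural space, spinal cord)
    with subject-level variability; a compact convolutional neural network
    engine trained with stochastic gradient descent and Nesterov momentum for
    binary, multi-class and distance-regression tasks; a sequential
    four-stage binary classification cascade with a sliding-window switching
    rule and traffic-light display state; a subject-grouped nested
    cross-validation and cross-testing harness with accuracy, MAPE, MAE and
    ROC/AUC metrics; an analytic needle-to-dura surface detector; and
    Grad-CAM saliency maps for trained classifiers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pROC,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
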