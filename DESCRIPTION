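Package: ssenet
Title: Spike-and-Slab Elastic Net Classification with Spatial Priors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Fits logistic-regression classifiers with spike-and-slab
    elastic net priors by EM coordinate descent, optionally placing an
    intrinsic autoregressive (IAR) prior on the logit prior inclusion
    probabilities so that variable selection borrows strength across a
    spatial neighbourhood (e.g. a 2-D image lattice or an atlas adjacency).
    Includes stratified k-fold cross-validation with deviance-minimising
    selection over (spike, slab) scale grids, binary-classification
    metrics (accuracy, sensitivity, specificity, PPV, NPV, Matthews
    correlation coefficient, F1), a generator for spatially correlated
    lattice predictor images with rare binary outcomes, and a harness that
    runs multi-model simulation studies and tabulates average prediction
    error and classification performance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    methods,
    stats,
    utils,
    rlang,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    ggplot2,
    generics,
    glmnet,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
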