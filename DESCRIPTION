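Package: painmvpa
Title: Multivariate Decoding of Chronic Pain from fMRI Contrast Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for two-group fMRI decoding
    studies of chronic pain. Generates synthetic cohorts of masked contrast
    maps (and optionally raw block-design BOLD time series) with planted
    group effects; fits first-level general linear models with an
    HRF-convolved boxcar regressor, discrete-cosine high-pass filtering and
    AR(1) prewhitening; trains sparse Bayesian logistic-regression
    classifiers with automatic relevance determination under leave-one-out
    cross-validation; and assesses performance with permutation tests,
    beta-posterior accuracy intervals, selection-count FDR inference, and
    the companion univariate voxelwise and demographic statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    nortest
Config/testthat/edition: 3
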