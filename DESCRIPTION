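Package: wsimil
Title: Weakly Supervised Multiple-Instance Classification of Histopathology Section Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: End-to-end weakly supervised classification of digitized
    histopathology tissue-section scans. Provides deterministic overlapping
    patch tiling with zero padding and bilinear downsizing, two-stage patch
    quality control (an artifact/background convolutional filter followed by
    an Otsu tissue-fraction rule), a compact convolutional patch classifier
    trained under multiple-instance weak section labels, majority-style
    patch-to-section aggregation, patient-level k-fold cross-validation with
    a full binary-metric suite (including Matthews correlation and rank-based
    AUC), Cohen's kappa for interobserver agreement, Grad-CAM heatmaps for
    model interpretation, and a seeded synthetic cohort generator that
    renders H&E-like section scans with known ground-truth masks so the
    whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
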