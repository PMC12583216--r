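Package: aacquant
Title: Automated Abdominal Aortic Calcification Scoring from Lateral Radiographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage automated quantification of abdominal aortic
    calcification (AAC) on lateral lumbar radiographs. Implements the
    Kauppila AAC-24 semi-quantitative scoring system (per-segment grading,
    totals, severity tiers, and mask-based automatic scoring), an
    encoder-decoder convolutional network for L1-L5 vertebra segmentation,
    anatomy-driven region-of-interest extraction, a residual convolutional
    network with spatial and channel squeeze-and-excitation attention that
    regresses the continuous AAC score, gradient-weighted class-activation
    mapping for model explanation, and a full agreement/accuracy evaluation
    suite (MAE, MSE, Spearman correlation, R-squared, bootstrap confidence
    intervals, ICC(2,1), weighted kappa, severity-stratified classification
    metrics). A synthetic radiograph phantom generator with known
    vertebral anatomy and per-segment calcification provides labelled,
    license-free data so that every stage is testable end to end. The
    convolutional network engine (im2col convolutions, instance
    normalisation, attention, SGD/Adam training) is implemented in the
    package via Rcpp.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    Rcpp,
    EBImage,
    png,
    tiff,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
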