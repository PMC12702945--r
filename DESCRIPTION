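Package: enetcaem
Title: Lightweight Multi-Scale Attention Networks for Plant Disease Image
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Builds, trains and evaluates a lightweight convolutional
    classifier for leaf- and fruit-disease images, based on a reduced
    EfficientNetB0 backbone augmented with multi-scale efficient channel
    attention, a channel context module, a light atrous spatial pyramid
    pooling head, learnable mixed pooling and per-block learnable stochastic
    depth. Includes exact parameter and multiply-accumulate accounting for
    the assembled networks, a seeded augmentation and class-balancing
    pipeline with stratified splitting, label-smoothed training under a
    cosine-annealed Adam schedule, per-class evaluation metrics with
    stratified k-fold cross-validation, and a synthetic lesion-image
    generator so every stage is testable without external data. All forward
    and backward tensor operations are implemented in-package on top of
    'RcppArmadillo'.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    png,
    yaml,
    jsonlite,
    EBImage
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
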