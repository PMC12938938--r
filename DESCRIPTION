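Package: gptnext
Title: Lightweight Transformer-Inspired CNN with Exemplar Deep Feature Engineering
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Implements GPTNeXt, a lightweight convolutional image classifier that
    borrows transformer design principles (patchify stem, pre-layer-norm blocks,
    GELU, dual residual shortcuts, inverted bottlenecks), together with a
    patch-based exemplar deep feature engineering pipeline: global-average-pool
    features are extracted from the full image and nine overlapping 112x112
    patches, concatenated to a 12,800-dimensional descriptor, reduced by
    iterative neighborhood component analysis (INCA) feature selection fitted on
    the training split only, and classified with kNN, SVM and LDA. Includes the
    full evaluation stack (confusion matrices, accuracy/UAR/UAP/F1, per-class
    sensitivity and specificity, Wilson score confidence intervals, McNemar
    tests), a seeded synthetic multi-scale image generator for end-to-end
    testing without external data, and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    e1071,
    MASS,
    png,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
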