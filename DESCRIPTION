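Package: loopcaps
Title: Capsule Networks for Predicting YY1-Mediated Chromatin Loops from
    Paired DNA Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains and evaluates a capsule-network classifier that decides
    whether two YY1-binding-site DNA sequences form a chromatin loop. Paired
    sequences are one-hot encoded and passed through a weight-shared encoder
    (multi-scale 1-D convolutions, a fusion convolution, and a bidirectional
    gated recurrent unit), then through a primary capsule layer and a
    two-capsule digit layer coupled by dynamic routing-by-agreement; training
    minimises the capsule margin loss with Adam and early stopping. Includes
    a planted-motif synthetic data generator so the full pipeline can be
    trained and benchmarked without external downloads, stratified k-fold
    cross-validation, threshold-free evaluation (ROC AUC, precision-recall
    AUC), cross-cell-type transfer evaluation, and capsule-feature export
    for low-dimensional visualisation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    Rcpp,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
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
    Biostrings,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
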