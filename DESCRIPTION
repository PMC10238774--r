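Package: qcsanet
Title: Quaternion Channel-Spatial Attention Networks for Binary Medical Image Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quaternion-valued convolutional residual networks augmented with
    channel and spatial attention gates, for binary classification of
    radiograph-like images. Provides exact quaternion algebra, Hamilton-product
    and rotation-form quaternion convolutions with hand-derived gradients,
    channel/spatial attention modules, a four-block residual classifier, a
    synthetic chest-X-ray-like dataset generator, a seeded Adam training loop,
    and a full binary-classifier metric suite (accuracy, precision, recall,
    F1, specificity, ROC AUC, Cohen's kappa).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
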