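Package: compressnet
Title: Teacher-Student Compression of Convolutional Image Classifiers
Version: 0.1.0
Authors@R:
    person("compressnet", "maintainers", email = "compressnet@example.org",
           role = c("aut", "cre"))
Description: A desk-scale toolkit for compressing convolutional image
    classifiers by a three-step pipeline: supervised pre-training and
    fine-tuning, knowledge transfer from a frozen teacher by matching the
    hidden feature vector, and top-down layer-wise filter pruning ranked by
    the reconstruction error each filter's removal induces in the next
    layer's feature map, with transfer-regularized retraining after every
    cut. Includes the matching train/test image augmentation pipeline
    (random scale, aspect ratio, crop, resize), a deterministic synthetic
    glyph-image generator for end-to-end testing without external data,
    macro top-k evaluation over repeated stratified splits, and a
    YAML-configured command line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
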