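Package: savannaseg
Title: Semantic Segmentation of Savanna Tree Species from RGB Orthomosaics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A desk-scale, fully tested pipeline for convolutional semantic
    segmentation of species-rich tree canopies in very-high-resolution RGB
    orthomosaics. Provides a seeded synthetic-scene generator emulating
    strongly imbalanced, patchy vegetation classes with class-specific fine
    texture; non-overlapping tiling with spatially separated train/validation/
    test splits; label-consistent geometric and photometric augmentation;
    inverse-power class weighting with weighted categorical cross-entropy;
    small configurable encoder-decoder architectures (U-Net, FC-DenseNet,
    DeepLabv3+) trained with Adam and early stopping; LOESS-smoothed selection
    of the best epoch by validation mIoU; offset-tiled 16-layer majority-vote
    inference; confusion-matrix accuracy metrics (per-class precision, recall,
    F1, overall accuracy, Cohen's kappa, mIoU); and per-class landscape
    metrics (mean patch area, total class area, smallest-circumscribing-circle
    compactness) with linear regressions of class F1 against each metric.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    yaml,
    jsonlite,
    stats,
    utils,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
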