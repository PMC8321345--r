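Package: wsiseg
Title: Deeply Supervised U-Net Segmentation of Tumors in Whole Slide Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Patch-based semantic segmentation of tumor tissue in whole slide
    images (WSI) and the downstream sectionwise Tumor/Normal decision. Provides
    U-Net encoder-decoder networks (a vanilla strided-convolution encoder and a
    34-layer residual encoder) with per-block score heads, trained with
    Focal-Loss under three strategies: plain, deep supervision of every decoder
    block against downsampled targets, and a learned linear merge of the
    per-block score maps. Includes annotation-coverage driven patch resampling
    for class imbalance, paired geometric/photometric augmentation, overlapping
    tile inference with probability-heatmap stitching, connected-region
    extraction with physical (square micrometre) area filtering, F-beta driven
    grid search over prediction and area thresholds, per-decoder-block
    truncated inference, and a synthetic histology-like fixture generator so
    the whole pipeline is testable end to end on CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    png,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
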