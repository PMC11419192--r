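Package: cherenkovseg
Title: Transfer Learning for Vessel Segmentation in Low-SNR Cherenkov Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A patch-based transfer-learning pipeline for segmenting vascular
    bio-morphological features in low signal-to-noise Cherenkov images acquired
    during radiotherapy. Provides a synthetic vascular phantom generator for two
    imaging domains (high-contrast fundus-like source images and noisy,
    beam-limited Cherenkov-like target images, including breathing-motion video
    streams), 224x224 patch extraction with a labeled-area retention filter,
    stochastic flip/rotation/noise augmentation, a residual encoder-decoder
    segmentation network trained with a weighted Dice plus cross-entropy
    objective via RMSProp, a pretrain-then-fine-tune transfer procedure with
    minimum-validation-loss checkpoint selection, overlap metrics (Dice, IoU,
    boundary IoU, largest connected component), and the rotation/noise
    robustness and sub-cumulative video-frame evaluation protocols.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    tidyr,
    ggplot2,
    generics,
    yaml,
    png,
    tiff,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
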