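Package: duckseg
Title: DUCK-Net Encoder-Decoder Networks for Binary Biomedical Image
    Segmentation
Version: 0.1.0
Authors@R:
    person("Duckseg", "Developers", email = "duckseg@posteo.net",
           role = c("aut", "cre"))
Description: Builds, trains, and evaluates DUCK-Net style convolutional
    encoder-decoder networks for binary segmentation of biomedical images,
    entirely on the CPU. Provides the DUCK multi-branch convolutional block
    and its constituent residual, midscope, widescope, and spatially
    separated blocks together with a gradient-footprint receptive-field
    oracle; a dual-path residual-downsampling encoder with addition-based
    skip connections; soft Dice loss and the standard overlap metrics (Dice,
    Jaccard, precision, recall, accuracy); the paired image/mask augmentation
    policy (flips, colour jitter, affine transforms); Lanczos image loading
    with mask binarization and reproducible 80:10:10 splits; and a seeded
    synthetic polyp-like dataset generator so the full pipeline is testable
    without external data or a GPU.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    jpeg,
    stats,
    utils,
    tools,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
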