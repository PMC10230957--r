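Package: uavpheno
Title: UAV Field Phenotyping of Rosette Crops from Multiband Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for estimating per-plant size (width, length)
    and relative chlorophyll content (SPAD) of row-planted rosette crops from
    nadir multiband (R, G, B, red-edge, near-infrared) imagery. Includes a
    photogrammetric ground-sampling-distance model mapping pixels to physical
    ground distances, a synthetic field-scene generator with exact ground
    truth, fixed-grid tiling with augmentation and train/test/validation
    splitting, a compact SRGAN-style super-resolution stage with PSNR/SSIM
    quality metrics, an encoder-decoder (UNet) semantic segmenter trained
    with categorical cross-entropy, connected-component trait extraction with
    multiple linear regression for SPAD, and an experiment runner comparing
    multispectral, RGB, and super-resolved RGB model variants.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tiff,
    yaml,
    withr,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
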