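Package: cellsharp
Title: GAN-Based Enhancement of Blurred Live-Cell Microscopy Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Restores sharp detail in out-of-focus brightfield and
    fluorescence micrographs with a conditional generative adversarial
    network trained on paired blurred/sharp images. Implements the full
    combined objective (adversarial, pixel-wise reconstruction, feature and
    Gram-matrix style perceptual terms, total-variation regularisation), a
    three-phase training schedule, tiled inference for arbitrarily large
    images, a classical unsharp-masking + CLAHE baseline, a synthetic
    cell-image generator producing paired degraded/sharp training sets, and
    an image-quality evaluation suite (NRMSE, PSNR, MS-SSIM, mutual
    information, entropy, and decorrelation-analysis resolution).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    png,
    tiff,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
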