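Package: clemosaic
Title: Rolling-Shutter-Resistant Mosaicking of Confocal Endomicroscopy Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building panoramic mosaics from probe-based confocal
    laser endomicroscopy (CLE) video under rolling-shutter distortion. Provides
    a seeded generator of synthetic glandular image sequences with known motion
    and ground-truth masks; a dual-path Gaussian U-Net gland segmenter with its
    ablation variants, training loop and segmentation metrics; mask-projection
    stability scoring and stable-frame selection; mask-constrained SIFT-style
    feature matching, RANSAC homography estimation, gain compensation and
    multi-band blending; and a video-stabilization evaluation battery (dense
    optical flow frame interpolation, accumulated camera paths, jitter
    variance, block-wise sharpness uniformity, SSIM/RMSE).
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
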