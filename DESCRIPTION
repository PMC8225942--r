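Package: icgflow
Title: Automated Quantitative Blood-Flow Analysis for Indocyanine Green Video Angiography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of indocyanine green (ICG)
    video angiography acquired during cerebrovascular bypass surgery.
    Provides a synthetic ICG-video generator with ground-truth wash-in
    dynamics, multi-task encoder-decoder vessel segmentation with joint
    negative log-likelihood loss and flip-based test-time averaging,
    SIFT keypoint registration of preoperative to postoperative vessel
    maps with ratio-test matching and RANSAC homography estimation,
    pyramid Horn-Schunck optical flow with per-vessel blood-flow
    direction classification, time-luminance curves and time-to-peak
    perfusion colour maps, and the agreement statistics (Cohen's kappa,
    percent agreement, paired t-test, normal Q-Q check) used to compare
    two raters of categorical flow direction.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    jsonlite,
    png,
    Rcpp,
    stats,
    tiff,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
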