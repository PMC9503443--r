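Package: facehr
Title: Facial Skin-Color Tracking for Exercise Heart-Rate Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A contactless (remote-photoplethysmography style) pipeline that
    tracks the mean color of a forehead patch across the frames of an exercise
    video in five color models (RGB chromaticity, HSV, YCbCr, CIE Lab, YUV)
    and relates the per-second color trajectories to exercise intensity
    expressed as percentage of age-predicted maximum heart rate (maxHR%).
    Includes frame preprocessing (blur detection, Wiener deconvolution,
    Gaussian denoising), face and forehead-patch localisation, chromaticity
    normalization, two-stage median/moving-average smoothing, lag-1
    multivariate autoregression per participant, a pooled polynomial
    regression across participants, and stationarity (ADF) and
    multicollinearity (VIF) diagnostics. A synthetic-video generator with
    known heart-rate/color coupling makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    car,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
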