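Package: follikel
Title: Speckle-Reducing Bilateral Filtering and B-Spline Snake
    Segmentation for Ultrasound Follicle Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reducing multiplicative speckle noise in 2-D
    ultrasound images and extracting follicle boundaries. Implements the
    conventional Gaussian bilateral filter and a speckle-reducing variant
    whose range kernel uses intensity differences normalized by the
    centre-pixel intensity, making smoothing strength invariant to local
    brightness under a multiplicative noise model. Includes an iterative
    filtering scheme, a piecewise-constant phantom generator with a
    multiplicative speckle simulator, despeckling quality metrics (NMSE,
    noise-suppression alpha, edge-preservation beta, Laplacian local
    contrast, Pratt's figure of merit), and a closed cubic B-spline active
    contour driven by a generalized gradient vector flow field for
    boundary extraction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
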