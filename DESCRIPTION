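Package: wingmorph
Title: Semi-Automated Wing Morphometrics and Species Identification for
    Drosophilid Flies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects the thirteen standard key points of a drosophilid wing
    photograph by exemplar-library template matching after a three-anchor
    affine alignment, traces five vein arcs with a fixed-endpoint active
    contour evolved on a constructed gradient image, derives sixteen
    morphometric variables (thirteen normalized centroid distances plus the
    costal index, C3 fringe and 5X index), and identifies the species by
    per-group Mahalanobis discriminant analysis with a chi-square 'unknown'
    rejection rule. A deterministic synthetic wing-image generator with exact
    ground truth supports benchmarking and calibration, and an exhaustive
    feature-subset search ranks variable combinations by leave-one-out
    accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    ggplot2,
    generics,
    jsonlite,
    png,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
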