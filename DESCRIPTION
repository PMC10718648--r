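Package: lodgekit
Title: Multi-Spectral UAV Imagery Preprocessing and Evaluation for Wheat Lodging Phenotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for preparing and scoring UAV multi-spectral imagery of
    wheat plots rated for lodging severity (scale 1-9). Implements
    intensity-based rigid band-to-band registration driven by a
    Gaussian-weighted mutual-information metric and a (1+1)-evolution
    strategy with a coarse-to-fine pyramid; two radiometric enhancement
    presets (haze/gamma adjustment and contrast-limit stretching); true-color
    and red-edge band composition plus NDVI, VARI, GARI and SABI vegetation
    indices; a full object-detection evaluation suite (IoU, greedy matching,
    non-maximum suppression, precision/recall/F1, per-class average
    precision, mAP over IoU thresholds, detection confusion matrix); and a
    seeded synthetic-scene generator so every stage is testable end-to-end
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
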