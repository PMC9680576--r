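Package: mvroi
Title: Region-of-Interest MV Imaging Apertures for Intrafraction Motion
    Correction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Designs control-point-specific region-of-interest apertures for
    megavoltage (MV) imaging during arc radiotherapy of cranial targets, and
    derives couch corrections from beam's-eye-view images. Provides a digital
    skull phantom generator, Siddon ray-traced digitally reconstructed
    radiographs (DRRs), mutual-information translation registration, a random
    aperture search with topographic-map thresholding, gradient polar-histogram
    and MI shift-surface information metrics, fiducial (BB) tracking, and
    closed-loop simulation of intrafraction motion with 2D/3D error evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    EBImage,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
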