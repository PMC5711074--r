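Package: wetmar
Title: Water-Equivalent Thickness Evaluation of CT Metal Artifact Reduction
    for Proton Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates axial CT scans of a hip-prosthesis water phantom with
    polychromatic beam hardening and photon starvation, applies an iterative
    sinogram-domain metal artifact reduction (MAR) of the O-MAR class, maps
    Hounsfield units to proton relative stopping power through a two-step
    stoichiometric calibration, and quantifies water-equivalent thickness
    (WET) errors against a metal-free reference as a function of beam
    direction. Includes Bethe-formula proton stopping powers for a built-in
    tissue and implant material library, parallel-beam Radon projectors and
    filtered back projection, and an end-to-end study driver producing the
    angular WET-difference tables and figures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    tibble,
    rlang,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    RNifti
Config/testthat/edition: 3
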