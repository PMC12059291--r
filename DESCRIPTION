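Package: cardioblur
Title: Simulating Cardiac-Motion Effects on Dose Distributions in
    Stereotactic Arrhythmia Radioablation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Desk-scale, fully synthetic simulation of how intrafraction
    cardiac motion degrades planned dose distributions during robotic
    stereotactic arrhythmia radioablation with respiratory motion tracking.
    Provides sinusoidal cardiac and Lujan-type (cos^6) respiratory motion
    models, a linear surrogate-to-target correlation-model tracking
    simulator with periodic refitting, an analytic spherical plan model,
    trajectory-occupancy dose blurring (including the closed-form arcsine
    kernel for sinusoidal motion), forward and inverse radiochromic-film
    dosimetry with a rational calibration curve, fluoroscopic marker
    tracking QA, and the standard film analyses: centroid error, isodose
    distance profiles, and global-normalization gamma pass rates.
License: MIT
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    graphics,
    Rcpp,
    jsonlite,
    minpack.lm,
    withr,
    EBImage,
    tiff,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
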