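Package: lsraman
Title: Processing Pipeline for Hyperspectral Line-Scanning Light-Sheet Raman Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for single-objective oblique-plane hyperspectral line-scanning
    Raman microscopy data: two-parameter spectral-axis calibration (coarse
    longpass-edge, fine peak-matching, and standard-spectrum recalibration),
    frame preprocessing (background subtraction, camera-tilt rotation, binning,
    illumination-gradient compensation, oblique-plane deskew), conversion of
    calibrated frames to Raman spectra with Richardson-Lucy beam-profile
    deconvolution and autofluorescence baseline subtraction, band-intensity
    mapping and false-colour composition, a small one-dimensional convolutional
    neural network for microplastic classification, retrospective
    cardiac-phase-synchronised reconstruction of periodic motion by
    cross-correlation against a reference video, and a synthetic instrument
    simulator (spectral libraries, microplastic scenes, and a beating-heart
    phantom under a full camera forward model) so that every stage is testable
    with known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    rlang,
    stats,
    tibble,
    tiff,
    png,
    utils,
    yaml
Suggests:
    jsonlite,
    tidyr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
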