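Package: fourfield
Title: Automatic Four-Field Box Radiotherapy Planning on Pelvic CT
Version: 0.3.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully automatic treatment planning chain for four-field box
    radiotherapy of the pelvis: treatment-couch detection and removal, external
    body contouring, three-fiducial marked-isocenter localization, bony-landmark
    driven beam-aperture design in beam's eye view with multileaf-collimator
    fitting, a simplified divergent-beam photon dose model, and non-negative
    least-squares beam-weight optimization to minimize dose heterogeneity in the
    treated volume. Ships a parametric synthetic pelvis-CT phantom generator
    with full ground truth so the whole chain can be exercised and validated
    end-to-end, plus segmentation-comparison metrics (Dice, mean surface
    distance, Hausdorff) and plan-quality metrics (hottest-1-cc dose, V95).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    oro.nifti,
    optparse
Config/testthat/edition: 3
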