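Package: artreg
Title: Articulated Non-Rigid Point-Set Registration for Markerless Pose Tracking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A generative framework for estimating and tracking 3D body pose
    from point clouds and depth sequences without training data. Combines
    topology-aware probabilistic non-rigid registration (coherent point drift
    with a locally-linear-embedding neighbourhood penalty, fitted by EM),
    hidden-point-removal visibility for single-view depth data, oriented
    bounding-box segment-volume validation with failure-case remedies, and
    segment-aware articulated ICP over a kinematic tree. Includes a synthetic
    articulated-body simulator with exact ground truth, depth-image
    pre-processing, and the standard joint-error and labeling-accuracy
    evaluation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
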