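Package: stereofish
Title: Stereo-Video Detection Matching, Sizing and Counting of Aquatic Organisms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A processing pipeline for stationary underwater stereo-video
    monitoring of marine organisms. Provides a calibrated pinhole-plus-distortion
    stereo camera model with epipolar rectification and triangulation, adaptive
    Gaussian-mixture background subtraction for activity-sequence extraction,
    detector-agnostic post-processing (confidence filtering, class-agnostic
    non-maximum suppression) and evaluation (confusion matrix with background
    class, precision/recall/F1 curves, average precision and mAP at IoU 0.5),
    a bounding-box stereo correspondence score with angle, overlap and class
    gates, corner-based size and distance measurement, checkerboard-based
    measurement-error validation, MaxN relative-abundance estimation with
    interval aggregation, VIAME-style annotation handling with per-image
    train/validation splitting, and a synthetic stereo-scene generator for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    yaml,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
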