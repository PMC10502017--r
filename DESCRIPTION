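Package: origamiflex
Title: Conformational Characterization of Dynamic DNA Origami Devices from
    Electron Micrographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A two-stage image-analysis pipeline for measuring the mechanics
    of dynamic DNA origami nanodevices (hinges and related multi-arm devices)
    from negative-stain transmission electron micrographs. Stage one detects
    isolated, well-folded particles as bounding boxes and filters them by
    confidence, non-maximum suppression and a bounding-box-size (aspect-ratio)
    filter; stage two estimates named structural keypoints (arm tips and the
    hinge vertex) on cropped particle images under a device schema and
    converts the resulting angle ensemble, via Boltzmann inversion, into a
    rotational free-energy landscape and torque profile. Detector and pose
    estimator are pluggable backends; classical image-processing reference
    backends are included, together with a synthetic micrograph generator
    with exact ground truth and evaluation tools (IoU matching,
    precision/recall/F1, angle and spatial errors, flip rate, and
    Kolmogorov-Smirnov comparison of angle distributions).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    png,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse,
    withr
Config/testthat/edition: 3
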