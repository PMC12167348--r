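Package: endonav
Title: Simulation Toolkit for Marker-Based Augmented-Reality Endoscope
    Navigation
Version: 0.1.0
Authors@R:
    person("endonav", "developers", email = "endonav@example.org",
           role = c("aut", "cre"))
Description: Tools for building and evaluating marker-based augmented-reality
    (AR) navigation for endoscopic skull-base surgery in simulation. Implements
    rigid-transform algebra, a pinhole-with-distortion camera model with
    planar-board (Zhang) intrinsic calibration, fiducial-board pose estimation
    robust to partial occlusion, paired-pose extrinsic calibration between an
    endoscope and an on-board tracking camera, automatic surface registration
    by robust point-to-plane ICP with a Tukey kernel, the classical
    infrared-tracked comparator with Procrustes fiducial registration, a
    synthetic phantom generator with seeded sensor noise models, and a
    projected target-registration-error (TRE) evaluation protocol comparing
    the two systems end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
SystemRequirements: C++17
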