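Package: fintrack3d
Title: Three-View 3D Posture Tracking and Gaze Analysis for Zebrafish Dyads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Post-detection tracking workflow for pairs of zebrafish filmed by
    three orthogonal cameras. Fits polynomial calibration maps between the
    camera views and world coordinates from bead-board correspondences,
    registers fish identities across views per frame by exhaustive search over
    reprojection cost, fuses per-frame skeletons with whole-video top-view
    identity labels, reconstructs 3D head/pec/tail skeletons, applies
    quality-control filters (anatomical length bounds, identity-swap and jump
    removal, gap interpolation, Savitzky-Golay smoothing), and computes dyadic
    gaze-asymmetry statistics. Includes a ground-truthed synthetic-data
    generator emulating the detector outputs so the whole pipeline can be run
    and validated without camera hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    zoo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
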