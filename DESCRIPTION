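Package: beadtrack4d
Title: Bead Trajectory Analysis for 4D Confocal Biofilm Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolchain for micron-scale bead movement in bacterial
    biofilms imaged by 4D (3D time-lapse) confocal microscopy. Provides
    feature-point detection and Brownian-motion particle linking for two-channel
    TIFF stacks, per-trajectory geometry and kinematics (trajectory length,
    life span, bounding box, velocity), origin-anchored mean-squared-
    displacement curves with quadratic trend fitting and diffusive-motion
    classification, voxel-intensity cellular-density weighting of velocities,
    velocity-versus-density regression at segment and trajectory scales, and a
    seeded synthetic 4D scene generator (Brownian beads in heterogeneous
    density fields rendered to image stacks) for ground-truth validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    minpack.lm,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
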