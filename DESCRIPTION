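Package: spinescan
Title: Torso Surface-Scan Analysis of Spinal Curvature
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies scoliosis from 3D torso surface scans without
    ionizing radiation. Reads polygon-file-format (PLY) surface meshes or
    stacks of pre-extracted transverse contour lines, locates the
    characteristic posterior dip marking the spinous-process tip on each
    transverse contour, fits a mid-sagittal reflection axis, corrects the
    estimated vertebral position for axial vertebral rotation with a
    sector-area offset formula, reconstructs the vertebral-column
    trajectory, fits coronal-plane polynomials with included angles at
    inflexion points, classifies lateral deviation and Cobb-angle
    severity, and rigidly matches trajectories from different sources
    with a bounded-rotation optimality score. A parametric synthetic
    torso generator with known ground truth supports validation of every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
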