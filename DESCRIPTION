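Package: gaze2mesh
Title: Map Mobile Eye-Tracker Fixations onto Photogrammetric 3D Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-hoc projection of mobile eye-tracking fixations onto a
    photogrammetrically reconstructed triangle mesh. Reads VisualSFM NVM
    scenes and PLY meshes, extracts fixation frames from a world-camera
    image sequence, casts each fixation's visual beam from its registered
    camera pose through the reported gaze point, and intersects it with the
    mesh (Moeller-Trumbore with an exhaustive reference path and an
    AABB-culled accelerated path). Writes a per-fixation projection table,
    a fixation point cloud in PLY, and a MeshLab project file. Ships a
    synthetic-scene harness (stimulus meshes, two-height reference camera
    rings, simulated observers with configurable angular gaze error, and
    surface dot targets) so the whole chain is testable with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
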