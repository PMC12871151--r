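Package: adhesionTFM
Title: Focal Adhesion Dynamics and Traction Force Microscopy from
    Live-Cell Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantification of integrin-based adhesion dynamics from
    two-channel TIRF time-lapse movies and of cell-generated traction
    from substrate bead displacements. Detects nascent adhesions as
    diffraction-limited point sources (Laplacian-of-Gaussian filtering,
    fixed-width isotropic Gaussian fitting, goodness-of-fit outlier
    removal), segments and classifies focal complexes and focal
    adhesions by area, links detections into trajectories with per-frame
    maturation status and lifetime statistics, estimates assembly and
    disassembly rate constants by adaptive-window log-linear regression
    with adjusted R-squared model selection, and reconstructs traction
    fields from bead displacements (cross-correlation particle tracking,
    normalized-median outlier filtering, Boussinesq-Cerruti boundary
    element forward model, L2-regularized inversion with L-curve corner
    selection). A synthetic-scene generator with exhaustively known
    ground truth makes every stage testable end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    clue,
    graphics,
    grDevices,
    igraph,
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
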