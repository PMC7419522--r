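Package: aerodep
Title: Markov Chain Modelling of Aerosol Deposition in Bifurcating Airway Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Discrete-state Markov chain model of inhaled-particle transport
    and deposition in a bifurcating airway tree. Provides closed-form
    per-segment deposition kernels for gravitational sedimentation, inertial
    impaction and Brownian diffusion, Poiseuille resistance-based flow
    partitioning, a sparse absorbing-chain solver for regional deposition and
    total escape, per-generation inlet flow-policy optimization, rigid body
    rotation and airway constriction experiments, a seeded synthetic
    asymmetric 3D airway-tree generator, and scintigraphy-style voxel
    projections of the deposition field.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    graphics,
    grDevices,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
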