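Package: lapjoint
Title: Mechanics of Inter-Tissue Adhesion in the Zebrafish Posterior Trunk
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A coarse-grained two-dimensional mechanical model of the
    zebrafish posterior trunk cross-section, in which the neural tube,
    the left and right presomitic mesoderm and the notochord are
    represented as pressurized mass-spring loops coupled by adhesive
    springs and resting on a rigid yolk surface. The package simulates
    overdamped relaxation to steady state, quantifies tissue shape
    (interfacial lengths and angles, bounding extents, areas, left-right
    asymmetry, curvature, surface tension profiles), drives parameter
    sweeps, genotype panels and unilateral perturbation experiments, and
    re-implements the accompanying microscopy quantification pipeline
    (local and global thresholding, matrix-element size sorting,
    medial-lateral distributions, anterior-posterior density profiles,
    photoconverted-spot deformation metrics, multi-pass block-matching
    displacement fields, Pratt circle fits and ratiometric gradients)
    together with seeded synthetic-image generators that provide ground
    truth for every quantification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
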