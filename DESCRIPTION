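Package: aerotree
Title: Age-Scaled Aerosol Deposition in the Pediatric Upper Airways
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reduced-order simulation of therapeutic aerosol transport and
    deposition in an idealized mouth-throat plus seven-generation bronchial
    tree, homothetically scaled from an adult to pediatric age points.
    Generates age- and device-specific inhalation waveforms (dry powder
    inhaler and nebulizer tidal breathing), routes Lagrangian particle
    ensembles through the tree with mechanistic impaction and sedimentation
    deposition probabilities and lobar flow weighting, and post-processes
    regional deposition efficiencies on the dimensionless Stokes-number
    axis: master-curve collapse diagnostics, Gaussian peak fitting for the
    conducting airways, and inversion of the Stokes number for the optimal
    aerosol diameter per age and device.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
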