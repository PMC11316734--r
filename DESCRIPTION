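Package: retinavasc
Title: Procedural Simulation of Retinal Vascular Networks and Hemodynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Procedural generation of fully connected arterial and venous
    retinal vascular networks using L-system seeding, constrained
    constructive optimisation governed by Murray's law, dedicated macula
    growth and capillary-bed closure. Solves one-dimensional Poiseuille
    blood flow with single inlet/outlet pressure boundary conditions,
    simulates fluorescein bolus transport, perturbs networks to model
    retinal vein occlusion and diabetic retinopathy, and extracts
    quantitative network morphometry. Networks are exchanged as Amira
    spatial-graph ASCII files or a documented JSON dialect, and can be
    rasterised into image volumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    igraph,
    jsonlite,
    yaml,
    deldir,
    FNN
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    optparse
Config/testthat/edition: 3
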