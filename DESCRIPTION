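Package: autoprog
Title: Autoprogressive Elastic-Modulus Imaging from Planar Force-Displacement Measurements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Quantitative quasi-static elastography by the autoprogressive (AutoP)
    method. Learns a nonparametric neural constitutive model of a deformed volume
    (a material property network paired with a spatial network of strain scale
    factors) from planar force-displacement measurements by iterating force-driven
    and displacement-driven finite-element analyses on hexahedral meshes. Includes
    a small-strain linear-momentum finite-element solver, a synthetic phantom
    simulator with a bias-style displacement error model, multi-plane training
    schedules with history windowing, spatial subsampling and weighting,
    information-theoretic convergence diagnostics (stress entropy, strain
    reversibility, stress convergence), Young's modulus image rendering in
    arbitrary planes, and what-if re-simulation with trained models.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    generics,
    jsonlite,
    stats,
    utils,
    tibble,
    ggplot2,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
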