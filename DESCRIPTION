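Package: tumorshape
Title: Shape Metrics and Surgical-Outcome Models for Brain Tumor Segmentations
Version: 0.1.0
Authors@R:
    person("tumorshape", "developers", email = "tumorshape@example.org",
           role = c("aut", "cre"))
Description: Computes radiomic shape scores for brain tumor segmentation
    masks: volume, triangulated surface area, contact surface area (CSA,
    the tumor surface exposed to brain parenchyma after subtracting the
    dura-abutting patch), and the sphericity index (SI, tumor surface area
    relative to the surface area of an equal-volume sphere).  Reads and
    writes NIfTI label volumes, extracts watertight isosurfaces with a
    built-in marching-cubes implementation, and measures dural contact by
    a configurable point-to-mesh distance rule.  Ships analytic 3D
    phantoms (balls, ellipsoids, cubes, lobulated and dura-clipped balls)
    with closed-form oracles, a seeded cohort simulator calibrated to
    published low-grade-glioma marginals, and the matching statistical
    battery: Shapiro-Wilk screening, Spearman/Mann-Whitney/Kruskal-Wallis
    univariable tests, Huber-weight robust linear models for extent of
    resection, and logistic models for postoperative focal deficits, plus
    a command-line interface tying the pipeline together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
SystemRequirements: C++17
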