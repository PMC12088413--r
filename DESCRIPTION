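Package: meioclock
Title: Synapsis Dynamics Against the HEI10 Accumulation Clock in Meiocyte Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies meiotic synapsis dynamics in fixed meiocyte image stacks
    using HEI10 focus accumulation as a developmental clock. Provides a synthetic
    three-channel (HEI10/ASY1/ZYP1) 3D microscopy generator with known ground
    truth, dual-threshold HEI10 quantification with 3D particle analysis,
    ASY1/ZYP1 skeleton length measurement on anisotropic voxel grids, axis
    coalignment geometry detection, calibration of accumulation-level staging
    cutoffs (background, plateau, late pachytene), and the genotype-comparison
    statistical layer: a Gamma generalized linear mixed model of exponential
    asynapsis decay with per-plant random intercepts, count regressions for
    multivalents, coalignment structures, synaptonemal-complex segments and
    crossover foci, Wald contrasts with Holm correction, and Nakagawa-style
    pseudo R-squared.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    Rcpp,
    glmmTMB,
    jsonlite,
    pracma,
    stats,
    tiff,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
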