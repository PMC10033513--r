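Package: hullcom
Title: Convex-Hull Volumetric Reconstruction of Body Mass and Centre of
    Mass, with Phylogenetic Comparative Tools
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Volumetric estimation of body mass and whole-body centre of
    mass (CoM) from posed three-dimensional body-segment geometry, for
    extant animals (closed skin-volume meshes) and fossils (minimum convex
    hulls of skeletal remains expanded by segment-specific hull-to-skin
    factors fitted on extant training data). Includes exact
    divergence-theorem mass properties for triangle meshes, an incremental
    3D convex hull, segment density scenarios, a 4 volume-model by 3
    density-scenario reconstruction grid, and the downstream phylogenetic
    comparative toolkit: Brownian-motion ancestral states with confidence
    intervals, phylogenetic generalised least squares with AICc and
    isometry classification, permutation-based phylogenetic ANOVA/ANCOVA,
    phylogenetic principal component analysis, phylomorphospace
    coordinates and Spearman rank correlations. A synthetic-body generator
    provides fully specified digital taxa with analytic ground truth so
    the whole pipeline is testable without any scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    nlme,
    phytools,
    withr,
    optparse
Config/testthat/edition: 3
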