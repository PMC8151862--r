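Package: erythrosim
Title: Red Blood Cell Aggregation, Sedimentation Curves, and Flow Shape
    Phase Diagrams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how red blood cell (RBC) rigidity and shape
    affect aggregate geometry and the erythrocyte sedimentation rate (ESR).
    Implements a two-dimensional ring-polymer (bead-spring) model of
    deformable and rigid red cells with overdamped Langevin dynamics and
    short-range adhesion; void ("hole") statistics of aggregated
    configurations on periodic domains with rank-based group comparisons;
    sub-pixel extraction of sedimentation curves from Westergren tube image
    stacks; microfluidic shape phase-diagram analysis, including
    croissant/slipper transition-point estimation and exponential
    acanthocyte deformability fits; and synthetic data generators that
    emulate all required inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp (>= 1.0.0),
    minpack.lm,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
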