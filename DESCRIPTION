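Package: seedscn
Title: Seed-Based Structural Covariance Network Analysis of Hippocampal
    Subdivisions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Seed-based structural covariance network (SCN) analysis of
    modulated gray-matter volume maps. Builds anterior and posterior
    hippocampal seed regions by long-axis world-coordinate cutoffs, fits
    voxel-wise ordinary-least-squares models of seed covariance within
    groups and seed-by-group interactions between groups, corrects
    cluster extent by Monte-Carlo simulation under estimated residual
    smoothness, intersects corrected maps (conjunction), tests spatial
    similarity of unthresholded t maps with a spin permutation null, and
    decomposes group-level Pearson correlations into per-subject
    structural-covariance integrity indices for clinical correlation.
    Includes a synthetic multi-subject cohort generator with planted
    seed-target covariance for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
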