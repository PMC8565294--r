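Package: fcnet
Title: Graph-Theoretic Analysis of Resting-State Functional Connectivity
    Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Constructs functional-connectivity networks from regional
    fMRI time series and analyses their topology with graph theory.
    Provides Fisher-z correlation matrices, sparsity-band thresholding,
    global and nodal network metrics (clustering, path length, global and
    local efficiency, degree, betweenness) with degree-preserving random
    null-model normalization (small-worldness), area-under-the-curve
    summaries across the sparsity band, and the group-comparison and
    brain-behavior statistical layer (Welch/Student t, chi-square,
    Mann-Whitney U, permutation tests, Pearson and partial correlations,
    Bonferroni-corrected nodal tests). Includes a synthetic cohort
    generator with known ground-truth group differences for end-to-end
    validation, and calibration utilities for type-I error and power.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
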