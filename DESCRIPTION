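Package: amyseg
Title: Multi-Atlas Diffeomorphic Segmentation of the Amygdala with
    Corrective Learning
Version: 0.1.0
Authors@R:
    person("amyseg", "developers", email = "amyseg@example.org",
           role = c("aut", "cre"))
Description: Automated volumetric segmentation of paired subcortical
    structures (amygdalae) from T1-weighted-like 3D images. Implements the
    full multi-atlas pipeline: white-matter-mode intensity normalization,
    rigid and multi-resolution diffeomorphic (demons-style) registration
    with a coarse/middle/fine schedule, iterative unbiased population
    template construction with probabilistic label maps and automatic
    per-hemisphere search regions, locally similarity-weighted label
    fusion, and AdaBoost-based detection and correction of systematic
    segmentation errors. Ships a seeded synthetic phantom generator with
    ground-truth labels, minimal NIfTI-1 input/output, and a segmentation
    evaluation battery (Dice, Jaccard, Pearson, two-way intraclass
    correlations).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
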