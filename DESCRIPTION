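Package: egbench
Title: Curation and Evaluation of Enhancer-Gene Interaction Benchmarks
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for building benchmarks of candidate enhancer-gene
    interactions from heterogeneous experimental evidence (ChIA-PET clusters,
    Hi-C loops, promoter capture Hi-C, cis-eQTLs and CRISPR perturbation
    screens) and for evaluating target-gene prediction methods against them.
    Positive element-gene pairs are derived by intersecting interaction
    anchors with distal regulatory elements and gene transcription start
    sites; negatives are generated under a distance-percentile rule; pairs
    are assigned to chromosome-balanced cross-validation groups to prevent
    positional leakage. Baseline (closest-gene, inverse-distance),
    signal-correlation, rank-combination and gradient-boosted supervised
    predictors are provided together with step-wise precision-recall
    evaluation and a fully seeded synthetic-fixture generator with planted
    ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    data.table,
    xgboost,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
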