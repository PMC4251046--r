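Package: OrderablePatterns
Title: Orderable Pairwise-Comparison Patterns of Gene Response to Multiple Treatments
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts true orders of gene response to multiple treatment
    groups from experiments with few replicates. Directional Wilcoxon
    rank-sum tests turn each pair of treatment groups into a ternary
    outcome (less, greater, tie); the collective outcomes form a gene's
    response pattern. Patterns free of the forbidden triple
    {x < z, x ~ y, y ~ z} are "orderable" and are the plausible true
    response orders. The package searches a per-gene ladder of candidate
    significance levels for the smallest level yielding a non-trivial
    orderable pattern, assigns multiple patterns per gene by bootstrap
    resampling of replicates, clusters genes by pattern label, computes
    orderable-fraction and structural-distance summary curves, and
    provides a hierarchical-clustering baseline, a synthetic-data
    generator with planted weak-order truths, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: GeneExpression, DifferentialExpression, Clustering,
    StatisticalMethod, Transcriptomics
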