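Package: sepsisSubtypes
Title: Discovery and Validation of Molecular Sepsis Subtypes from Gene
    Expression Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Unsupervised discovery of molecular subtypes in gene-expression
    cohorts of critically ill septic patients. Implements silhouette-driven
    selection of the number of clusters over random gene subsets, an iterative
    gene-enrichment tally, partitioning-around-medoids and Ward hierarchical
    co-clustering, permutation-based significance analysis of microarrays
    (SAM) with q-value gene selection, cluster verification by bootstrap
    co-clustering stability, bimodality-index mixture fits and principal
    components, nearest-medoid transfer of a subtype model to an independent
    cohort, and downstream clinical and pharmacogene comparisons. Includes a
    synthetic two-subtype cohort generator so the full pipeline is testable
    without microarray downloads.
License: MIT
Encoding: UTF-8
Imports:
    cluster,
    jsonlite,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
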