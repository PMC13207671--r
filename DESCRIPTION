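Package: scpda
Title: Single-Cell Proteomics Differential Abundance Pipeline
Version: 0.1.0
Authors@R: person("scpda", "maintainers", email = "scpda@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of single-cell proteome quantification
    matrices: procedural-blank background subtraction, sample-depth and
    replicate-detection filtering, log2 median-centering, left-censored
    (downshifted-normal) imputation of missing values, covariate-preserving
    empirical-Bayes batch correction, two-sample differential abundance
    calling with Benjamini-Hochberg FDR control, hypergeometric
    over-representation analysis, permutation GSEA, and Maximal Clique
    Centrality hub scoring on protein-protein interaction networks.
    Includes a seeded synthetic-data generator that emulates a two-group,
    two-batch single-cell design with intensity-dependent (left-censored)
    missingness, planted fold-changes, batch effects and procedural blanks,
    so every stage of the pipeline is verifiable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
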