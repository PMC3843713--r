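Package: anchornet
Title: Anchor-Gene Coexpression Networks from Knockout and Recombinant
    Inbred Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for tracing a single hub ("anchor") gene from a knockout
    microarray experiment to a phenotype-correlated coexpression network.
    Implements standardized pairwise array difference scores (S-scores) with
    empirical same/same calibration, one- and two-class SAM-style permutation
    tests with a median-FDR composite filter, k-means clustering of
    differential expression patterns, hypergeometric and score-threshold
    over-representation analysis of gene sets, anchor-gene and phenotype
    correlation screens across recombinant inbred panels, multi-list
    intersection network construction with probeset-to-gene collapsing, and
    network eigengene (first principal component) correlation with a
    behavioral phenotype.  A synthetic-data generator with planted ground
    truth supports calibration and recovery testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    igraph,
    yaml,
    fgsea
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
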