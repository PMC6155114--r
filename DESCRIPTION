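Package: gcnet
Title: Genetic Correlation Networks from Metagenome Gene Abundances
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds signed genetic correlation networks from gene-by-sample
    metagenome abundance tables: Spearman correlation with FDR control,
    network deconvolution of indirect correlations, random-matrix-theory
    (nearest-neighbour spacing distribution) selection of the similarity
    threshold, multi-resolution modularity clustering with a cluster
    hierarchy, hub and intra/inter-cluster role classification, negative-edge
    analysis, per-cluster functional enrichment, and guilt-by-association
    function prediction for genes with domains of unknown function. Includes
    a synthetic-data generator that plants recoverable cluster, hub,
    prevalence and environmental structure so every stage of the pipeline can
    be validated against a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
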