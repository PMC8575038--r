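Package: stratabench
Title: Benchmarking Knowledge-Driven and Dimensionality-Reduction
    Clustering for Disease Subtype Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A framework for discovering and evaluating molecular disease
    subtypes from bulk gene expression. Implements a network-driven pathway
    enrichment feature extractor that combines per-patient seed-gene
    selection, random walk with restart over a gene network, and pre-ranked
    gene set enrichment analysis to build sparse pathway-level patient
    embeddings; co-expression network construction with the scale-free
    topology criterion, topological overlap, module detection and
    eigen-genes; divisive (DIANA) and standard clustering algorithms; a
    five-criterion evaluation protocol (silhouette separability, resampled
    clustering stability, batch-aware subtype concordance, gene-module
    relevance, and survival relevance via Cox likelihood-ratio tests); and
    multi-objective Pareto-front model selection. A seeded synthetic-cohort
    generator with planted subtypes, batch effects, co-expression modules,
    aligned gene sets and cluster-dependent survival makes the full
    workflow testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    mclust,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    cluster,
    fgsea,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
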