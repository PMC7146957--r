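Package: gomclust
Title: Clustering of Enriched Gene Ontology Terms by Markov Clustering
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Condenses long, redundant lists of enriched Gene Ontology (GO)
    terms into non-overlapping functional clusters. Terms are connected in a
    similarity network weighted by the Jaccard or Overlap coefficient between
    their test-set gene members, and the network is partitioned with a
    deterministic Markov Clustering (MCL) implementation. Includes parsers for
    OBO 1.2 ontology files and for the output formats of common GO enrichment
    tools (BiNGO, g:Profiler GEM, agriGO, GOrilla, and a documented generic
    layout), cluster-quality evaluation via within-cluster similarity
    distributions, reconstruction of the GO hierarchy inside each cluster,
    sub-clustering of selected clusters, Cytoscape SIF export, plotting, a
    planted-block synthetic fixture generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ggplot2,
    igraph,
    jsonlite,
    optparse,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
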