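Package: plastomics
Title: Comparative Plastome Phylogenomics: Diversity Scans, Tree-Space
    Concordance, and Structural Variation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for comparative analysis of annotated plastid
    genomes (plastomes): sliding-window nucleotide diversity and GC
    content with complete deletion of missing data, extraction of coding,
    intergenic-spacer and intron loci from annotated quadripartite
    plastomes, distance-based gene-tree estimation, gene-tree/species-tree
    concordance via the Kendall-Colijn tree metric with
    principal-coordinate projection and hierarchical cluster discovery,
    majority-rule consensus and genus-monophyly screening,
    inverted-repeat junction mapping, and scanning of large shared
    insertions/deletions. Includes a fully seeded synthetic-data
    generator (Yule species trees, multispecies-coalescent gene trees,
    HKY+Gamma sequence evolution, quadripartite plastome assembly with
    injected structural variants) so every stage can be exercised and
    validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape (>= 5.0),
    BiocGenerics,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
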