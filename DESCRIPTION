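Package: cernakit
Title: Competing Endogenous RNA Network Inference from RNA-Seq Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for inferring lncRNA-miRNA-mRNA
    competing endogenous RNA (ceRNA) networks from bulk RNA-seq count data,
    built around a two-tissue, two-condition ligament injury design.
    Provides median-of-ratios size factors and FPKM normalization, a
    negative-binomial Wald test for differential expression with
    Benjamini-Hochberg FDR control, positional classification of lncRNAs
    (lincRNA, antisense, intronic, sense) against protein-coding gene
    models, a shared-miRNA hypergeometric test with co-expression filtering
    for ceRNA pair calling, hub-node ranking by Degree and Maximal Clique
    Centrality, hypergeometric term over-representation analysis, and
    relative qPCR quantification by the 2^-ddCt method. A seeded
    synthetic-data generator with ground-truth labels makes every stage
    testable without sequencing data.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    DESeq2,
    GenomicRanges,
    IRanges,
    rtracklayer,
    S4Vectors,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
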