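Package: methylodecode
Title: Methylome Decoding by Signal Detection, Divergence Statistics, and
    Motif Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Calls differentially methylated positions (DMPs) in
    whole-genome bisulfite data by Hellinger-divergence signal detection
    against a pooled wild-type centroid, aggregates DMPs into
    differentially methylated genes (DMGs) with count, density,
    fold-change and FDR filters, discriminates epigenetic states by
    Ward clustering and PCA-LDA on gene-level divergence vectors,
    selects network hubs by k-means clustering of node centralities,
    and discovers 14-bp methylation sequence motifs scored by a
    pairwise log2 match-count statistic with a Dirichlet-multinomial
    Monte-Carlo randomness test. Ships a ground-truthed synthetic
    methylome simulator so every stage is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    MASS,
    S4Vectors,
    ape,
    dplyr,
    fitdistrplus,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
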