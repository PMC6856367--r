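Package: medipdmr
Title: Window-Based Differential Methylation Analysis for MeDIP-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for genome-wide differential DNA
    methylation analysis of MeDIP-seq data. Partitions a reference genome
    into fixed-width windows annotated with CpG counts, counts mapped reads
    into windows, equalizes depths by subsampling, tests each window for
    two-group differential coverage with a negative-binomial exact test,
    calls differentially methylated regions (DMRs) by merging significant
    windows and extending their edges at a relaxed threshold, summarizes
    DMR genomic features (CpG density, length, chromosomal clusters, gene
    proximity), builds a permutation null distribution for the DMR count,
    and projects held-out samples onto a principal-component biomarker
    space fit on RPKM read depth over DMR windows. A seeded synthetic-data
    generator with spiked hyper- and hypomethylated regions supports
    end-to-end testing without sequencing data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    methods,
    ggplot2,
    generics,
    stats,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    jsonlite,
    yaml,
    knitr,
    rmarkdown,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
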