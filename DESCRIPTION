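Package: riboassoc
Title: Identify Ribosome-Associated and Putatively Translated lncRNAs from Ribosome Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for cataloguing long non-coding RNAs
    (lncRNAs) by their association with ribosomes across multiple ribosome
    profiling (Ribo-seq) datasets. Per dataset, transcripts are classified as
    ribosome-associated or ribosome-free by comparing their ribosome density
    against an empirical cutoff taken at the 90th percentile of 3'UTR
    densities, and putative lncRNA ORFs are scored with three coding-potential
    metrics: a transformed fragment length organization similarity score
    (FLOSS), a scaled ribosome release score (RRS), and a frame-periodicity
    score based on the Kullback-Leibler divergence from the pooled CDS frame
    distribution. Evidence is integrated across datasets through an expression
    specificity score, the ribosomal association index (RAI), composite
    RAI-by-specificity scores and a weighted translation score, yielding a
    catalog of noribo-, ribo- and trans-lncRNAs with enrichment statistics.
    A seeded simulator generates synthetic transcriptomes and footprint
    alignments with ground-truth labels for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    stats,
    utils,
    yaml,
    Biostrings,
    Rsamtools,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
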