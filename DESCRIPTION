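Package: isoscope
Title: Structural Annotation of Full-Length Transcriptomes from Long Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-style toolkit for the structural annotation of
    full-length (Iso-Seq style) transcriptomes. Classifies circular consensus
    reads into full-length non-chimeric (FLNC) reads by primer and poly(A)
    signals, collapses spliced alignments into nonredundant isoform models by
    junction chain, filters 5'-degraded and unsupported isoforms, groups
    isoforms into strand-specific gene loci and calls novel loci and isoforms
    against a reference annotation, classifies alternative-splicing events
    into exact and approximate-boundary categories, detects alternative
    polyadenylation sites from clustered 3' ends, calls candidate fusion
    transcripts from multi-gene alignments, and screens long noncoding RNA
    candidates. A seeded synthetic-data generator produces a toy genome,
    annotation, reads, alignments and ground truth so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    igraph,
    IRanges,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    GenomicAlignments,
    Rsamtools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
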