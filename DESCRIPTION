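Package: IntronEss
Title: Intron Structure and Gene Essentiality Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the relationship between intron structure and
    gene essentiality. Extracts introns from a genome (FASTA) and annotation
    (GFF3) using the longest-coding-sequence transcript of each gene, labels
    genes from study-level essentiality call tables, and computes per-intron
    sequence features (GC-motif density, GC content with motif content
    subtracted, unusual 5'/3' splice boundaries, Takai-Jones CpG islands) plus
    a seven-entry per-gene feature vector. Implements a convolutional
    sequence classifier over fixed first/last intron windows with gene-grouped
    splits, class-balanced training and grid-search cross-validation; gene-level
    majority and double-majority scoring with ROC/AUC evaluation; and an
    ensemble feed-forward network over the seven gene features. A synthetic
    corpus generator plants class-dependent intron-length, GC-density,
    splice-dialect and motif structure so the full pipeline can be exercised
    and validated end to end without external genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
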