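Package: madswalk
Title: MADS-Box Gene Family Identification and Read-Based Gene Model Completion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Toolkit for genome-wide identification and curation of MADS-box
    transcription factor genes from draft genome assemblies. Provides
    profile-based scanning for the MADS (M) and keratin-like (K) domains,
    pairwise and progressive alignment primitives, an iterative
    transcriptome-read walking algorithm that completes truncated gene models
    from short reads, open-reading-frame completion with before/after
    reporting, neighbor-joining phylogenetics with bootstrap support and
    clade assignment, IUPAC degenerate-motif scanning of promoter and intron
    sequences, and 2^-ddCt relative expression analysis with hierarchical
    clustering. A synthetic-data generator with recorded ground truth makes
    every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    data.table,
    ape,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
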