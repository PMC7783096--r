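Package: famcensus
Title: Gene-Family Census, Phylogeny and Expression Analysis Toolkit
Version: 0.9.0
Authors@R:
    person("Family", "Census", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for genome-wide gene-family surveys of
    receptor-like kinase families defined by protein domain content
    (malectin and malectin-like domain proteins and similar families).
    Locates domain instances in a proteome, builds ordered
    domain-architecture strings and classifies them into superclades;
    constructs neighbor-joining trees with bootstrap support and extracts
    supported clades; detects tandem-duplication gene clusters and intron
    statistics from gene models; normalises multi-experiment RNA-seq
    counts with a variance-stabilising transform, computes the tau
    tissue-specificity index and peak-tissue groupings; and infers
    guide-gene co-expression networks by mutual information with CLR
    background correction. Ships a synthetic-data generator with planted
    truth so the full pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    GenomicRanges,
    S4Vectors,
    igraph,
    jsonlite,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
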