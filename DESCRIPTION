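Package: pyroprofile
Title: Gene Expression Profiling from Barcoded Pyrosequencing Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A self-contained pipeline for building stage-resolved gene
    expression profiles from multiplexed, barcode-labelled pyrosequencing
    reads, as used in early-developmental transcriptomics of marine
    invertebrates. Covers MID demultiplexing, adaptor/quality/duplicate read
    cleaning, best-hit read-to-contig assignment, per-million count
    normalization, a Poisson counting-error reliability filter with
    confidence "stars" (count-depth and Dixon Q-test outlier stars),
    centroid-linkage hierarchical clustering with Cluster 3.0 compatible
    output, and cross-platform validation of temporal dynamics against qPCR
    series normalized to internal control genes. Ships a synthetic-data
    generator emulating a seven-stage developmental design so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
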