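Package: regrewire
Title: Comparative ChIP-chip Peak Calling and Regulatory Network
    Rewiring Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for comparative ChIP-chip tiling-array
    studies of transcriptional regulatory network rewiring between two
    yeast species. Implements peak detection on probe-level log2
    enrichment tracks (Gaussian blur, per-base-pair natural cubic spline
    interpolation, greedy 1 bp peak extraction with a 600 bp masking
    window, Z-score significance calling), promoter-based target
    assignment, cross-species regulon comparison under an orthology map
    with hypergeometric statistics, GO enrichment with hierarchy
    expansion, TF-GO / TF-TF / TF-kinase network construction with Pajek
    export, spaced-triplet (mini-motif) enrichment scanning against
    composition-preserving randomized sequences, transcription-factor
    co-occupancy covariance and peak-distance analysis, and a fully
    seeded synthetic two-species data generator with planted ground
    truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    methods,
    withr,
    igraph,
    S4Vectors,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
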