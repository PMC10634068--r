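Package: methylhet
Title: Read-Level DNA Methylation Heterogeneity from Bisulfite Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates genome-wide DNA methylation heterogeneity from
    read-level methylation patterns (epialleles) in bisulfite or EM-seq
    alignments. Implements three Hill-number (attribute-diversity) scores
    of order 2 - abundance-based, pairwise-similarity-based and
    phylogenetic-tree-based - together with seven published comparison
    scores (methylation entropy, epipolymorphism, PDR, FDRP, qFDRP, MHL
    and methylation concurrence), sliding-window genome screening with
    tile-level bedGraph/CSV tracks, calling of differentially
    heterogeneous and differentially methylated regions and genes, and a
    seed-deterministic synthetic methylome generator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    BiocGenerics,
    GenomeInfoDb,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    rtracklayer,
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    ape
Config/testthat/edition: 3
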