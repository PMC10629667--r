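Package: tassel
Title: Stranding, Artifact Detection and Strand-Aware Merging for Long-Read
    cDNA Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for Oxford Nanopore cDNA long-read transcriptomics.
    Implements SLURP, a primer-based method that infers the strand of origin
    of unstranded cDNA long reads from terminal kit-primer evidence and emits
    a consistently oriented library; a detector for the reverse-transcriptase
    template-switch palindrome artifact (terminal primer-pair screen,
    self-complementarity fold, paired-base fraction and mountain profile)
    together with SAM supplementary-alignment filtering and coverage
    accounting; TASSEL, a strand-aware merge of short-read-derived and
    stranded long-read-derived transcript models into a non-redundant
    consensus transcriptome with coverage-stringency filtering and source
    tracking; gffcompare-style class codes, sensitivity and precision,
    transcript end proximity and segmentation metrics; and a seeded simulator
    of ONT direct-cDNA libraries with an ERCC-like 92-transcript spike-in
    ladder used as ground truth throughout.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    BiocGenerics,
    rtracklayer,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
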