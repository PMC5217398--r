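Package: dgetag
Title: SAGE-Style Digital Gene Expression Tag Profiling
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for restriction-anchored digital gene expression (DGE)
    tag profiling of the NlaIII/MmeI type, in which each transcript is
    represented by a 21 nt tag (CATG anchor plus 17 nt) whose count
    measures expression. The package builds a virtual reference tag
    library from a transcript FASTA, cleans raw tag reads through the
    standard five-filter scheme, maps clean tags to genes with a
    perfect-match-first one-mismatch policy, normalizes counts to tags
    per million, calls differential expression between two libraries
    with the exact Audic-Claverie test under Benjamini-Hochberg FDR
    control, decomposes calls across two stress durations, and performs
    hypergeometric GO-term enrichment against the reference background.
    A fully parameterized simulator produces synthetic transcriptomes
    and noisy tag libraries with ground-truth manifests so that every
    stage is testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    Biostrings,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
biocViews: GeneExpression, DifferentialExpression, Sequencing,
    Transcriptomics, SAGE
RoxygenNote: 7.3.3
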