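Package: spidmir
Title: Small RNA-Seq Pipeline for Heat- and Spermidine-Responsive miRNAs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, desk-scale small RNA sequencing pipeline for
    identifying plant miRNAs responsive to high-temperature stress and
    exogenous spermidine across four single-library conditions (CW, CS, HW,
    HS). Implements phred64-aware seven-rule read filtering with
    removal-category accounting, unique-tag collapsing, exact genome mapping,
    hierarchical small RNA annotation against a precursor/mature reference,
    simplified hairpin-based novel miRNA prediction, transcripts-per-million
    normalization with the Audic-Claverie exact tag-count test for per-pair
    differential expression, four-pair Venn responsiveness screening,
    complementarity-based plant miRNA target prediction, hypergeometric
    term enrichment, and growth-trait summary contrasts. Ships a synthetic
    data generator with a ground-truth manifest so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    BiocGenerics,
    Biostrings,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
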