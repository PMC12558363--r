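Package: snSplice
Title: Cell-Type-Resolved Differential Splicing from Single-Nucleus Long Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Case-control differential splicing analysis for cell-type-resolved
    single-nucleus long-read RNA-seq. Provides UMI deduplication by edit
    distance, rare intron-chain filtering, discovery of alternative internal
    exons, classification of reads into inclusion and exclusion events,
    percent-spliced-in (PSI) and delta-PSI testing with Fisher's exact test,
    chi-squared gating and Benjamini-Yekutieli FDR control, a per-sample
    support/ordering/age-matched filter cascade, alternative donor and
    acceptor splice-site usage testing, pseudobulk masking and
    splicing-versus-expression overlap analyses, a junction-spanning
    hybridization-capture probe designer, and a synthetic read-table
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    data.table,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
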