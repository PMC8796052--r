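Package: tribeclip
Title: Target Identification for m6A Reader Proteins from HyperTRIBE and iCLIP Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for identifying mRNA targets of an m6A reader
    protein from HyperTRIBE A-to-I editing data and iCLIP crosslink data, and
    for characterising the sequence-motif geography around methylation and
    crosslink sites. Provides beta-binomial differential-editing calls with
    replicate-support and SNP filters, crosslink-site collapsing and
    IDR-dependence splits, log-odds PWM scanning with location-matched
    backgrounds, motif distance profiles and gene-body observed/expected
    enrichment, gradient-boosted motif-window classification, target-set
    comparison across methods, and a seeded synthetic-data generator that
    emulates the statistical structure of the real data so every stage is
    testable without downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
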