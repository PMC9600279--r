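Package: cpxscreen
Title: Genome-Wide Screening of CpxR Binding Sites and Regulon Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A regulon-prediction pipeline for the bacterial CpxRA
    two-component envelope stress response. Builds position-specific
    scoring matrices (PSSMs) from curated CpxR binding sites
    (consensus GTAAA-N5-6-GTAAA, with a middle-base duplication rule
    converting 15-bp sites to 16-bp ones), scans bacterial genomes on
    both strands, calibrates an adaptive mean-minus-SD score
    threshold, maps hits into strand-aware promoter windows (700 bp
    upstream to 100 bp downstream of start codons), classifies
    candidate genes into four binding-site location groups, and calls
    regulation from qRT-PCR delta-delta-Ct fold-change tables using a
    2-fold rule. Includes seeded synthetic-data generators (training
    sites, genomes with planted boxes and matching annotations, Ct
    tables) so every stage is testable against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
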