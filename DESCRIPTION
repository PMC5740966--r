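Package: srnapipe
Title: Small RNA-Seq Profiling of Paired Tumor/Normal Libraries with
    miRNA Editing Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end small non-coding RNA sequencing pipeline for
    paired tumor/non-tumor cohorts: adapter trimming and quality
    filtering of raw reads, collapsing to unique tags, hierarchical
    annotation of tags into small RNA classes (miRNA, rRNA, tRNA,
    snRNA, snoRNA, scRNA, repeats, degraded mRNA fragments) with
    library-composition statistics, TPM-normalised miRNA expression
    profiling with per-pair fold-change classes and paired t-tests,
    detection of single-mismatch miRNA variants as candidate A-to-I
    editing events with seed-region classification, hypergeometric
    pathway enrichment of predicted miRNA targets with Bonferroni
    correction, and a paired-cohort read simulator with full ground
    truth for validation. Published per-cohort summary tables are
    packaged as fixtures for exact regression tests.
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
    rtracklayer,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
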