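Package: cnvburden
Title: Multi-Caller CNV Consensus Calling and Case-Control Burden Association
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A whole-genome copy-number-variation (CNV) case-control analysis
    pipeline: quality filtering of CNVnator calls, per-sample multi-caller
    consensus merging by reciprocal overlap, breakpoint-union segmentation of
    the genome into atomic regions, exclusion of centromere/telomere/segmental
    duplication regions, per-region Fisher exact association with odds ratios,
    a global gain/loss burden summary, and multi-cohort locus selection with
    batch-consistency and validation-cohort gates. Includes a synthetic cohort
    and callset simulator that emulates planted risk loci, imperfect callers
    with breakpoint jitter and false calls, and CNVnator-style quality fields,
    so every stage of the pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
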