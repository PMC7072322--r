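Package: earlygc
Title: Somatic Mutation Analysis for Early Gastric Cancer Tumor/Normal Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Somatic variant filtering, CpG-aware background mutation-rate
    modelling with per-gene significance testing, Bethesda microsatellite
    instability classification, mutation-spectrum tabulation, and cohort
    contingency statistics for tumor/normal sequencing studies of early
    (non-invasive) gastric cancer. Includes a synthetic tumor/normal cohort
    generator so that every stage of the analysis is testable without
    access to patient-level sequencing data.
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
    vcfR,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
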