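Package: cnotarget
Title: Post-Transcriptional Target Discovery for the CCR4-NOT Deadenylase Subunit CNOT7
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery and validation pipeline for transcripts targeted by the
    CCR4-NOT deadenylase subunit CNOT7 through their 3'UTRs. Scans 3'UTR
    sequences for degenerate RNA-binding-protein motifs (CPE, PUM, NRE, CPSF,
    AU-rich elements), tests motif enrichment in target gene sets against a
    genome background with a random-resampling permutation null, calls
    CNOT7-anticorrelated transcripts from knockdown/overexpression expression
    data, calls RIP-enriched transcripts from immunoprecipitation count
    tables, runs a genome-wide tripartite CPE/CPSF/NRE screen with Venn
    accounting, and evaluates inverse-correlation-weighted gene signatures by
    median-split Kaplan-Meier survival stratification. A synthetic-data module
    generates every pipeline input with planted, recorded ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
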