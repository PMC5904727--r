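Package: xenomir
Title: Screening Putative Foreign miRNAs in Host Small RNA-Seq Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for deciding whether putative foreign ("xenomiR")
    microRNAs detected in host small RNA sequencing data are genuine
    dietary signals or artifacts. Implements count-table screening with
    reads-per-million cutoffs and sample-prevalence inclusion criteria,
    classification of candidate sequences against host references
    (exact, partial >= 15 nt, near-match, antisense), a per-candidate
    triage combining abundance, annotation status and host-sequence
    evidence, the stringent host-subtraction read filter recommended for
    xenomiR claims, and a synthetic-data generator with ground-truth
    labels so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
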