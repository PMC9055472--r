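Package: colonlp
Title: Rule-Based Text Mining of Colonoscopy and Pathology Reports for
    Quality Indicators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts paired free-text colonoscopy and pathology reports
    into structured polyp findings using a pluggable lexicon and
    regular-expression concept matching, links biopsy-marked findings
    sentences to pathology specimens by sequence, and rolls the extracted
    findings up into colonoscopy quality indicators: adenoma and sessile
    serrated lesion detection rates (overall and per endoscopist),
    advanced-lesion rates, and 2020 US Multi-Society Task Force
    surveillance-interval assignments via a versioned decision table.
    Includes a precision/recall/accuracy/F1 evaluation harness against
    gold annotations and a synthetic paired-report generator with gold
    labels so the whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
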