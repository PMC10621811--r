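Package: cviscreen
Title: Screening and Validation Analytics for a Timed Card-Matching
    Visual Search Test for Cerebral Visual Impairment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for a timed card-matching visual-search
    screener for cerebral visual impairment (CVI) related visual issues in
    children aged 5-18.  Provides a serial-search performance simulator with
    an age-dependent speed trend and a latent visual-search deficit,
    age-stratified normative percentile thresholds, a six-threshold
    screening decision rule, scorers for two paper-and-pencil cancellation
    tests (teddy bear and six-letter), and the diagnostic-agreement
    statistics (Cohen's kappa with a marginal null-variance test,
    sensitivity and specificity with Wald confidence intervals) used to
    validate such screeners against reference classifications.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
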