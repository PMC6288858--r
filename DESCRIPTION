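Package: linkerr
Title: Linkage Error Impact on Time-to-Event Analyses of Linked Registry Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how probabilistic record-linkage errors (false and
    missed matches) bias effect estimates and precision in time-to-event
    analyses of linked health and demographic surveillance (HDSS) data. The
    package generates a gold-standard-linked synthetic world (a person
    registry, clinic and sero-survey encounter records with configurable
    identifier corruption, and a proportional-hazards time-to-HIV-care-
    registration outcome), links encounters to the registry with a
    Fellegi-Sunter model using permutation-invariant Jaro-Winkler name
    comparison, builds analytic datasets at percentile-based match-score
    thresholds, quantifies sensitivity, positive predictive value and
    false-match rate against the gold standard, compares true, false and
    missed matches with standardised differences, and contrasts Cox
    proportional-hazards estimates of the testing-modality effect across
    thresholds with the gold-standard fit.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    survival,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
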