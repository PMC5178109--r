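Package: clariped
Title: Pediatric Emergency Risk Classification with an Age-Stratified
    Vital-Sign Score and Discriminator Catalog
Version: 0.1.0
Authors@R:
    person("Triage", "Tools", email = "triage-tools@example.org",
           role = c("aut", "cre"))
Description: Implements a five-level pediatric emergency triage
    (risk classification) system built from two steps: an age-stratified
    vital-sign score (VIPE, 0-12) computed from respiratory rate, heart
    rate, oxygen saturation and a fever correction of elevated heart
    rate, and a data-driven catalog of clinical discriminators that can
    only upgrade the assigned urgency.  Each urgency color maps to a
    maximum waiting time and care destination.  Includes multi-rater
    agreement statistics (Fleiss' kappa with per-category components),
    urgency-by-resource-use contingency analysis with Pearson and
    Monte-Carlo chi-square tests, synthetic cohort and rater-matrix
    generators for end-to-end testing, CSV readers/writers, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
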