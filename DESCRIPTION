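Package: ocsplus
Title: Scoring, Normative Cut-Offs and Psychometrics for the OCS-Plus Tablet Cognitive Screen
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trial-level scoring of the ten OCS-Plus subtasks from structured
    session logs, derivation of age-stratified normative impairment cut-offs
    (z-score and centile based), cognitive domain summative scores, a
    psychometric validation toolkit (bootstrapped split-half reliability,
    attenuation-corrected convergent/divergent validity, paired test-retest
    statistics with reliable change indices, cohort harmonisation checks), a
    synthetic session and cohort simulator with known ground truth, and an
    automated per-participant impairment report.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
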