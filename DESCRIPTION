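Package: clinchange
Title: Detecting and Scoring Moments of Change in Clinical Notes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A semi-rule-based text-mining pipeline for psychiatric electronic
    health records that finds sentences describing a change in a patient's state
    on transdiagnostic outcome themes (symptom reduction, social functioning,
    general well-being, patient experience), assigns each sentence a signed
    sentiment score, and aggregates scores per patient or admission trajectory.
    Sentences are split and annotated, filtered by pluggable phrase lexicons for
    theme and change cues (including comparative adjective forms), screened by
    five contextual checks (current, not hypothetical, concerns the patient, not
    negated, change grammatically concerns the theme), and scored by multiplying
    theme polarity with change direction. Includes an evaluation harness against
    span-level accept/reject annotations, a synthetic annotated-corpus generator
    with constructive ground truth, and encoders for structured EHR change
    categories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
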