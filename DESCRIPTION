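Package: qoatrend
Title: Activity-Trend Analysis of 30-Day Readmission Risk from Wrist Actigraphy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Processing pipeline for continuous wrist-worn accelerometer
    monitoring of chronic obstructive pulmonary disease (COPD) patients after
    hospital discharge. Converts raw tri-axial 20 Hz recordings into
    minute-wise activity indices over noon-to-noon days, applies a wear-time
    validity rule, derives day-to-day regularity indices and the quality of
    activity (QoA) score, computes weighted trend statistics, raises
    rule-based 30-day readmission alerts under configurable criteria
    profiles, and evaluates alerts against clinical event logs with
    sensitivity, precision, miss-rate and false-discovery-rate summaries. A
    synthetic cohort generator with circadian structure, non-wear gaps and
    injected pre-event deterioration provides ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
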