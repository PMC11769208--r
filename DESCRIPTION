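Package: msdrisk
Title: Multicriteria Prediction of Long-Term Musculoskeletal Disorder Risk
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts long-term musculoskeletal disorder (MSD) risk in the
    neck, shoulders and elbows of workers performing patient-handling and
    other lifting tasks. Combines age-dependent population baseline
    prevalence curves (quadratic in age, with a time-shift prognosis
    transform) with a weighted multicriteria model in which demographic,
    technique and motion-derived criteria scale the baseline probability
    through normalized weight coefficients and element likelihoods. Includes
    extraction of range of motion, maximum joint moment, cumulative joint
    moment and side-symmetry shares from joint angle/moment time series, a
    synthetic cohort and lifting-motion generator for end-to-end testing,
    packaged criteria tables and baseline curves, and a command-line
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
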