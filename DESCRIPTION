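Package: erdeep
Title: Objective EEG Evaluation of Acoustic Tinnitus Therapy via ERD/ERS
    Maps and Deep Spectrum Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, reproducible pipeline for evaluating auditory
    discrimination therapy in tinnitus patients from event-locked EEG.
    Keypress-locked epochs are mapped to event-related
    (de)synchronization (ERD/ERS) time-frequency maps with a complex
    Gaussian continuous wavelet transform and pre-event baseline
    correction; scalogram images are summarized into 1280-dimensional
    deep spectrum features by a MobileNet-V2-style convolutional
    backbone with global average pooling; groups and sessions are then
    compared with Lilliefors-screened Student's t-test matrices, a
    difference-in-differences treatment-effect estimator, and
    centroid/Euclidean-distance analysis. A synthetic cohort generator
    emulating the study design (two groups, two sessions, five auditory
    stimuli repeated with keypress responses) makes every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    nortest,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
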