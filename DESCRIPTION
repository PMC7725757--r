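Package: gazemetrics
Title: End-to-End Eye-Tracking Analysis: Event Detection, Parameter
    Extraction and Group Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A format-agnostic toolkit for analysing eye-tracking
    recordings. Converts EyeLink-, SMI- and Tobii-style text exports to a
    common trial table, aggregates experiments into a queryable CSV or
    SQLite store, detects oculomotor events (noise-based blink onset and
    offset refinement, dispersion-threshold I-DT fixations,
    velocity-threshold I-VT saccades, and median-threshold microsaccades
    with a six-sample minimum), extracts 21 eye-movement parameters per
    trial with area-of-interest and control-stimulus support, runs mixed,
    repeated-measures and n-way ANOVA plus pairwise Student and Welch t
    tests across subject and stimulus groups, and renders fixation plots,
    smoothed gaze heat maps, microsaccade traces and main-sequence plots.
    A synthetic-trial generator with planted ground-truth events makes the
    whole pipeline testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    DBI,
    RSQLite,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
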