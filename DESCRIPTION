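Package: gazexpect
Title: Expectation-Guided Gaze Analysis for Face-Viewing Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for analysing expectation effects on eye
    movements during face viewing: simulation of 1000-Hz monocular gaze
    with main-sequence saccades and ground-truth events, velocity- and
    acceleration-based saccade/fixation/blink detection, region-of-interest
    scoring (predictive saccades, fixation order, fixation counts, dwell
    time), preregistered-style trial and participant exclusion rules,
    behavioural scores (reaction-time facilitation, perceived-face-identity
    index), and a statistical battery including repeated-measures ANOVA
    with Greenhouse-Geisser correction, exact Wilcoxon signed-rank tests,
    and cluster-robust goodness-of-fit and proportion tests for
    within-participant binary data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
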