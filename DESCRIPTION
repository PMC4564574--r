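Package: pupilflow
Title: Pupillometry Pipelines for Cognitive-Control Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for task-evoked pupillometry in
    cognitive-control experiments. Reads eye-tracker sample and event tables,
    combines the two eyes into one pupil trace, pads and linearly interpolates
    blink artifacts, cuts baseline-corrected per-trial epochs with
    interpolation-based trial exclusion, averages condition waveforms, runs
    sample-wise paired t-tests with a contiguity-based cluster threshold, and
    scores 2-Back, Stroop and Number Switch behavior (interference effects,
    switch costs, outlier trims, square-root error transform). An
    individual-differences layer provides correlation matrices, forward
    stepwise regression and two-level repeated-measures contrasts with partial
    eta squared. A synthetic-study generator with a unit-peak pupil response
    kernel, AR(1) noise, a blink process and effort-coupled behavior supports
    parameter-recovery testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
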