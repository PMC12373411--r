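Package: kinewell
Title: Wearable Kinematics, Well-Being Classification and Pre-Post Statistics for Exergame Cohort Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for community exergame intervention cohorts in
    older adults. Extracts physical-activity metrics from body-worn inertial
    measurement unit (IMU) streams (z-score peak detection, action count,
    maximum and root-mean-square acceleration, MET-based energy expenditure),
    scores a 14-item Mental Health Continuum-Short Form adaptation and
    classifies participants as mentally well versus moderate, aggregates
    daily nutrition logs into weekly trends, and reproduces the pre/post
    inferential layer (two-tailed paired t-tests, pooled-SD Cohen's d,
    percent change, group-stratified weekly metric trends). A seeded
    synthetic-data generator emulates the study design (5 sensor sites,
    3 games, 4 weekly sessions, 4 arms, 48 participants with 30 survey
    completers) so every stage is testable without raw sensor data.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
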