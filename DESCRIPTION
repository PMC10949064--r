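Package: torportools
Title: Behaviour-Validated Torpor Bout Detection and Hibernation Cohort Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for segmenting hibernation skin-temperature and behavioural
    records into torpor bouts and arousals, calibrating the skin-temperature
    threshold that defines them (threshold sweep, continuous two-segment
    breakpoint regression, many-to-one duration comparison against a
    behavioural reference), and computing downstream cohort statistics:
    mixed models on bout durations, repeatability of individual differences,
    Poisson/binomial/gamma treatment-contrast models, Welch tests and Cohen's
    d, plus a huddle-size index from binary huddle masks. Includes a seeded
    synthetic hibernation-cohort generator so every stage is testable without
    datalogger or video data, and a deterministic end-to-end pipeline runner.
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
    lme4,
    lmerTest,
    mvtnorm,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
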