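Package: prepshift
Title: Time-and-Motion Decomposition and Task-Shifting Cost Analysis for
    PrEP Service Delivery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing time-and-motion records of HIV
    pre-exposure prophylaxis (PrEP) provision in primary care.  Reads and
    consolidates health-care-worker (HCW) interaction records, classifies
    clinic visits, decomposes recorded visit durations into
    activity-level time needs by ordinary least squares with
    information-criterion model selection, values the estimated times
    with cadre salary schedules, propagates uncertainty through interval
    arithmetic on confidence-interval and salary bounds, and evaluates
    task-shifting scenarios (per-visit cost ranges, savings against a
    nurse base case, and freed nurse time).  Includes a seeded
    synthetic-record generator with the same statistical structure for
    testing and simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    sandwich,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr,
    ggplot2
Config/testthat/edition: 3
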