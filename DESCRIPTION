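Package: emawear
Title: Smartphone EMA and Wearable Analysis for Adolescent Depression Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for intensive longitudinal studies that combine twice-daily
    smartphone ecological momentary assessment (EMA) of mood and anxiety with
    wearable sleep and step tracking. Provides a synthetic cohort generator
    emulating a two-week adolescent depression study design, EMA ingest with
    prompt-window assignment and compliance accounting, mood-variability
    statistics (RMSSD, coefficient of variation, intraclass correlation),
    Fitbit-style sleep log and minute-level step parsing with nap
    classification and sleep-masked daily step totals, and a registry of
    linear mixed-effects models with lagged mood, stress, sleep and activity
    predictors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    readr,
    jsonlite,
    yaml,
    lme4,
    lmerTest,
    car,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    e1071
Config/testthat/edition: 3
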