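Package: ventzones
Title: Breath-by-Breath Ventilation Zone Analysis for Non-Inferiority Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing breath-by-breath ventilator data from
    randomized trials of closed-loop ventilation. Classifies every breath
    into predefined quality-of-breathing zones (optimal, acceptable,
    critical) from tidal volume per predicted body weight, maximum airway
    pressure, end-tidal CO2 and pulse-oximetry saturation; aggregates
    per-subject zone proportions by breaths and by time, hypoxemia
    incidence and duration endpoints; performs ratio-of-means
    non-inferiority inference with delta-method confidence intervals,
    mean differences, odds ratios, Kaplan-Meier/log-rank comparisons and
    subgroup interaction tests; reproduces trial design arithmetic
    (noncentral-t sample size, simulation-based power); and generates
    complete synthetic two-arm trials with realistic breath streams for
    end-to-end pipeline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
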