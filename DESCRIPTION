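Package: rumentherm
Title: Rumen-Reticular Temperature Dynamics at Estrus and Ovulation in Dairy Cows
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Extracts baseline-relative thermal features (positive area under
    the curve, maximum positive and negative temperature change) from hourly
    rumen-reticular temperature of dairy cows around automated-activity-monitor
    detected estrus and ultrasound-confirmed ovulation. Includes water-intake
    transient correction, a rolling 5-day hourly baseline, temperature-humidity
    index computation with period maxima, a standardized-change alerting system
    over 0.5-3 SD thresholds with interval statistics, event accounting, and a
    fully ground-truthed synthetic herd generator so the whole pipeline is
    testable without farm data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
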