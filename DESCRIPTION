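Package: careflow
Title: Time-Perspective Process Mining for Acute Care Pathways
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for mining time-critical clinical processes from event
    logs. Provides a hierarchical classification-and-coding scheme for
    clinical activities with multi-level abstraction, readers and writers for
    XES (IEEE 1849) and CSV event logs, a rule engine for validating and
    filtering acute-stroke patient traces, cohort splitting with
    observation-window truncation, discovery of dependency graphs with a
    heuristics-miner style dependency measure, timeline enhancement that
    places activities at their median minutes from hospital arrival, and
    automated computation of acute ischemic stroke performance indicators
    such as door-to-needle and imaging-to-needle time. A reproducible
    synthetic stroke-pathway simulator with known ground truth supports
    testing and demonstration without hospital data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
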