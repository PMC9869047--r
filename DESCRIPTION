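Package: careflowr
Title: Interactive Process Indicators for Clinical Care Pathways
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Process-mining engine for clinical event logs: reads care-episode
    logs in a tabular dialect, validates data quality, discovers timed
    directly-follows workflow models with artificial start/end nodes, enhances
    models with clamped heat-map colour layers, compares cohorts through
    difference maps with per-node Mann-Whitney significance, clusters traces
    by quality-threshold clustering under Levenshtein, topological and
    heuristic distances, and derives PSA state traces. Ships a seedable
    synthetic prostate-cancer pathway generator and a command-line interface,
    so every analysis is reproducible without access to hospital data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    rlang,
    readr,
    jsonlite,
    ggplot2,
    igraph,
    optparse,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
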