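Package: crossimpact
Title: Cross-Impact Matrix and Network Influence Analysis for Goal Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for semi-quantitative cross-impact analysis of interacting
    goal systems such as the Sustainable Development Goals. Constructs and
    validates seven-point cross-impact matrices (integer scores from strongly
    restricting, -3, to strongly promoting, +3), computes first-order,
    second-order and total network influence of each goal, ranks goals and
    reports rank shifts, extracts focal-goal perspectives including feedback
    loops, classifies and summarises interaction composition, reconciles
    multi-group workshop scores into a consensus matrix, and correlates
    direction-recoded indicator time series with paired observations. Includes
    seeded synthetic-data generators for matrices, group scorings and
    indicator series, readers and writers for CSV matrices, edge lists,
    GraphML and JSON reports, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
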