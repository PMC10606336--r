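Package: carenet
Title: Queueing-Network and Entropy Analysis of Hospital Care Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models a hospital care system as an M/M/c queueing network of
    units, solves the traffic equations for effective arrival rates, and
    evaluates candidate unit poolings by Monte-Carlo bed-occupancy
    simulation (supply-demand mismatch and nurse-reallocation days) and by
    three Shannon-entropy measures: arrival entropy of relative demand,
    positional entropy of patient classes, and decision-structure entropy of
    hierarchy, network and hub coordination strategies with or without
    information aggregation. Includes a built-in perinatology care-system
    fixture, a synthetic-scenario generator with controllable inter-unit
    demand correlation, scenario configuration I/O, and report assembly
    that ranks designs by total entropy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
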