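Package: aeforage
Title: Simulation and Analysis of Adjusting-Energy Reinforcement Schedules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A discrete-event simulator and analysis toolkit for operant
    foraging experiments in which energy expenditure, rather than response
    count, is the controlling variable. Implements the interresponse energy
    (IRE) statistic for pecks on a touch surface, the adjusting-energy (AE)
    reinforcement schedule with block-wise titration against a fixed-ratio
    (FR) alternative, forced-choice correction trials, session stability
    criteria, and analytics over simulated logs: indifference points between
    AE and FR requirements, IRE distributions, and total energy per
    reinforcement (E/RFT). Configurable synthetic agents (logistic choosers
    with lognormal peck kinematics, plus deterministic test agents) stand in
    for live subjects.
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
    grid,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
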