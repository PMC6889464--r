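Package: qsgame
Title: Evolutionary Game Dynamics of Quorum-Sensing Cooperation in
    Bacterial Public-Goods Games
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the evolutionary analysis of quorum-sensing
    cooperation in bacterial populations modelled as an N-player public
    goods game with probabilistic exclusion (punishment) of defectors.
    Implements exact expected payoffs for cooperator, defector, and
    conditional-defector strategies under multinomial group sampling, a
    Monte-Carlo payoff oracle, replicator dynamics with numerical
    integration and oscillation detection, fixed-point location and
    stability classification on the strategy simplex, the log-ratio
    relative-fitness statistic used in pairwise competition assays, Wilson
    interval estimation for colony-count frequency tables, grid-search
    calibration of game parameters against observed frequency
    trajectories, and seeded generators that emulate serial-passage and
    competition experiments, including a finite-population Wright-Fisher
    style simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
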