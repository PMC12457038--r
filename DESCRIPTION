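Package: egovalence
Title: Markov Models of Emotional Valence Dynamics Under Egosyntonicity
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for a discrete-time Markov model of the valence of the
    dominant emotion, in which transitions between negative and positive
    valence are modulated by egosyntonicity (agreement between valence and
    internal mood) and by attention to external events. Provides exact
    construction of the eight-state joint transition matrix by two independent
    routes, stationary-distribution analysis with a closed-form expression for
    the steady-state probability of positive valence, seeded Monte Carlo
    simulation of trajectories with empirical egosyntonicity statistics,
    parameter sweeps over the five model parameters, and classification of
    parameter combinations into four behavioural phenotypes (balanced happy,
    self-deluded, chronically troubled, troubled happy) with phase-diagram
    heat maps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
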