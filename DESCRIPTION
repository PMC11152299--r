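Package: dynroute
Title: Dynamic Routing Model: Reinforcement Learning on a Rectified
    Resistive State Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements a model-based reinforcement-learning agent whose world
    model is a directed, rectified (diode-like) resistive network inspired by
    gap-junction connectivity between Kenyon cell axons in the insect mushroom
    body. State transitions are learned latently as conductances, reward states
    are grounded, and current flow solved by nodal analysis drives subgoal and
    action selection, which permits fast learning under sparse (goal-only)
    reward. Ships three benchmark environments (the Taxi grid world, a
    procedurally generated Voronoi navigation world, and a linear Petri-dish
    olfactory conditioning task for larval Drosophila), a tabular Q-learning
    baseline, and metrics for convergence, graph recovery, and maggot
    preference/learning indexes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    rlang,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    igraph,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
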