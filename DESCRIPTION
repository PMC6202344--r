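Package: dyadlearn
Title: Hierarchically Distributed Dyadic Learning: Simulation, Metrics and
    Fitting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Agent-based simulation of joint learning in hierarchical dyads.
    A high-level "strategy" agent chooses among information filters by
    attraction-based reinforcement learning with softmax (logistic) choice,
    while a low-level "operational" agent estimates the value of filtered
    three-component inputs with a simple perceptron trained by the delta
    rule.  The package provides the task environment (uniform integer
    inputs, a permuted weight vector, two-of-three disclosure filters), a
    vectorised cohort simulator with ablation variants (fixed filter, frozen
    perceptron weights, a statistically sophisticated strategy agent),
    performance metrics (learning curves, disclosed-information rate, switch
    rate, sensitivity score, median-split clustering, convergence
    classification, Hartigan's dip test of unimodality with Monte Carlo
    p-values), and grid-search parameter estimation by normalised mean
    square deviation between simulated and target trajectory curves.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
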