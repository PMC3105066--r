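Package: metanorms
Title: Metanorms Games on Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic agent-based simulator and analytic companion model for
    Axelrod-style norms and metanorms games generalized to arbitrary undirected
    interaction networks. Provides seeded network generators (Barabasi-Albert,
    Watts ring-rewiring, Erdos-Renyi) and topology statistics (degree
    distribution, clustering by degree, interconnectedness as triplets per
    agent), a three-stage defect/punish/meta-punish game with roulette-wheel
    selection and bit-flip mutation, closed-form expected payoffs with mutant
    gradients and evolutionary-stable-state identification, and experiment
    drivers for long-run zone-occupancy sweeps and empirical drift maps.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
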