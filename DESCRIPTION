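Package: qvoter
Title: Generalized Threshold q-Voter Model of Social Response
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the threshold q-voter model of opinion dynamics on the
    complete graph in which agents respond to a randomly sampled influence
    group of size q with conformity, anticonformity, independence, or
    uniformity/congruence. Conformity requires at least r of the q sampled
    agents to oppose the target's opinion; anticonformity requires at least w
    of them to share it. The package provides exact per-step transition rates
    for finite and infinite populations, mean-field stationary analysis of the
    order-disorder phase transition (critical nonconformity p*, spinodals,
    transition-type classification, critical independence fraction z*,
    critical conformity majority r*, tricritical panel size q*), an exact
    finite-population birth-death Markov chain solver for the probability
    density of the opinion imbalance, and a compiled Monte Carlo agent-based
    simulator with random sequential updating. The three engines
    cross-validate each other.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
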