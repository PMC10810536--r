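Package: targetctrl
Title: Target Controllability Analysis of Effective Connectivity Networks
Version: 0.1.0
Authors@R:
    person("targetctrl", "maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Gramian-based network control theory for signed, asymmetric
    effective connectivity (EC) matrices of brain regions. Generates synthetic
    cohorts of stable EC matrices with realistic density, sign balance and
    inter-subject consistency; computes controllability and observability
    Gramians, worst-case and pairwise minimum control energies, and verified
    minimum-energy control inputs; ranks candidate driver nodes by graph and
    energy centralities; and orchestrates cohort-level analyses of
    resting-state-network target control, driver enrichment, rank aggregation,
    accessibility weighting and perturbation sensitivity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
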