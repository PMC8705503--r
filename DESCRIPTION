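Package: rnahit
Title: Hitting Times of High-Fidelity Replicators in RNA Sequence Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact stochastic simulation (Gillespie) of a replicating RNA
    population on fitness, similarity and fidelity landscapes over Hamming
    sequence space, with template-directed polymerization under a binomial
    mutation kernel, duplex formation/dissociation, decay, surface ("clay")
    chemistries and vesicle compartmentalization. Provides online detectors
    for first-passage (hitting) times of replicator establishment with right
    censoring, a Weibull proportional-hazards likelihood for censored hitting
    times, variance-based global sensitivity analysis via high dimensional
    model representation (HDMR), and a mean-field mass-action ODE reduction
    with fixed-point stability analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    deSolve,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    survival,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
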