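Package: phenflux
Title: Markov Chain Inference of Phenotypic Cell-State Transitions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of discrete-time Markov transition matrices over
    marker-defined phenotypic cell states from time-resolved proportion data of
    purified subpopulations. Transition probabilities are recovered by taking
    regularized matrix roots of phenotype proportion matrices and averaging
    across measurement days. On top of the estimated chain the package computes
    stationary (equilibrium) compositions, relaxation times from arbitrary
    initial admixtures, transient/recurrent/absorbing state classification,
    Krackhardt hierarchy scores of the transition graph, and per-marker
    coarse-grained independence analyses. A seeded synthetic-data generator
    simulates pure-start multipotency assays (with optional state-specific
    proliferation and per-cell multinomial phenotyping) so the full pipeline is
    testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
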