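Package: funcstate
Title: Multiscale Emergent Functional States of Weighted Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes diffusion propagators (heat kernels) on weighted
    undirected networks, the emergent functional states they induce at a
    tunable propagation scale, Von Neumann spectral entropy of the network
    Gibbs state, modularity-based functional modules across rescaled
    diffusion time scales, and randomized-weight configuration-model
    (RWCM) nulls for sparse weighted networks such as fungal and slime
    mould transport networks. Includes synthetic network generators,
    edge-list and adjacency I/O, multiscale sweep orchestration, and
    ggplot2 visualisations; results are returned as tibbles.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
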