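Package: sangnet
Title: G-Network and Stochastic Automata Network Models of Gene Regulatory
    Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Models gene regulatory networks as G-networks (queueing networks
    with positive and negative customers, interpreted as activation and
    repression signals) and analyses them through the stochastic automata
    network (SAN) formalism. Provides product-form stationary distributions
    via the nonlinear traffic equations, Kronecker-structured assembly of the
    truncated global CTMC generator, transient joint distributions of gene
    pairs through a projection kernel with Pearson correlation trajectories,
    calibration of external arrival rates from mean mRNA expression levels,
    and a continuous-time stochastic simulator with empirical CDF
    diagnostics. Ships a five-gene telomere-maintenance network (normal and
    ALT conditions) as a built-in example.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
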