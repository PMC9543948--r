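Package: mothprune
Title: Sparse Neural Controllers for Simulated Hawkmoth Hovering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates planar two-segment hawkmoth hovering dynamics under
    thrust-vectored control, generates inverse-dynamics training data from
    20 ms constant-control strokes, trains feed-forward networks with
    arctangent hidden activations to predict the controls linking initial and
    final body states, and sequentially prunes the networks by weight
    magnitude -- either by manual re-zeroing or with persistent bi-directional
    binary masks -- to locate the sparsest network that still performs under a
    loss threshold. Includes Monte Carlo ensemble analysis of pruned-network
    populations: breakdown-sparsity detection, layer-sparsity and
    input-connectivity statistics, and closed-loop rollout evaluation of the
    learned controllers against the simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
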