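Package: lulcsim
Title: Land-Use and Land-Cover Change Scenario Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing historical land-use/land-cover (LULC) change
    between two dated categorical maps and simulating alternative future
    scenarios on a regular grid. Implements cross-tabulation of map pairs with
    minor-transition filtering and submodel grouping, derivation and screening
    of spatial driver variables by Cramer's V, multilayer-perceptron transition
    potential modelling with accuracy-rate and skill-measure statistics,
    Markov-chain demand projection with matrix annualisation, narrative-driven
    scenario parameterisation (constraints, incentives and forest-loss
    trajectories), demand-constrained ranked cell allocation, and map-agreement
    validation by overall kappa and per-class kappa index of agreement.
    A synthetic-landscape generator with planted transition matrices and driver
    responses allows the whole pipeline to be exercised and verified without
    external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    igraph,
    jsonlite,
    mgcv,
    stats,
    tools,
    utils,
    yaml
Suggests:
    e1071,
    nnet,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
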