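Package: easigp
Title: Interpretable Ensemble Genomic Prediction with Circos Visualisation
Version: 0.1.0
Authors@R: person("EasiGP", "Maintainers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Fits an ensemble of six genomic prediction models (rrBLUP, BayesB,
    Gaussian-kernel RKHS, random forest, support vector regression and a
    bipartite graph attention network) across many train/test prediction
    scenarios, attributes per-marker effects (model coefficients, Shapley
    values, impurity importance, Integrated Gradients) and pairwise
    marker-by-marker Shapley interactions, aggregates them across scenarios,
    and renders the inferred trait genetic architecture as a layered circos
    plot in genetic-map (centimorgan) coordinates. Includes preprocessing
    (population-wise modal imputation, phenotype filtering, windowed LD
    pruning, replicate concatenation) and a recombinant-inbred-line simulator
    (backcross plus selfing under the Haldane map function) with known
    additive and epistatic architecture for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
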