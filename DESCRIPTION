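Package: symnet
Title: Contemporaneous Symptom Network Analysis for Ordinal Patient-Reported Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation and inference for contemporaneous symptom networks from
    ordinal symptom-severity ratings such as the 13-item MD Anderson Symptom
    Inventory severity domain. Implements two-stage polychoric correlation
    estimation with positive-semidefinite repair, sparse partial-correlation
    network estimation by graphical lasso with extended-BIC model selection and
    covariate control, weighted-graph centrality indices (strength, closeness,
    betweenness, expected influence), the Spearman-based network density
    statistic, nodewise predictability, nonparametric bootstrap edge-weight
    confidence intervals, case-dropping stability (correlation-stability
    coefficient), bootstrapped difference tests, and permutation tests for
    subgroup density differences. Includes a latent-Gaussian synthetic-data
    generator with known sparse network structure, covariate effects, and
    subgroup density contrasts for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
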