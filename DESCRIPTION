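Package: idna
Title: Intraindividual Dynamic Network Analysis of Daily Symptom Ratings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates a person-specific dynamic symptom network from one
    individual's multivariate daily ratings. Each item is polynomially
    detrended in week-time, then every symptom at day t is regressed on all
    symptoms (including itself) at day t-1 with L1 (LASSO) regularization
    tuned by the corrected Akaike Information Criterion, yielding a sparse
    signed directed lag-1 network. The package prunes dynamically isolated
    nodes, computes standardized strength and betweenness centrality,
    detects community structure with a signed spin-glass method scored by
    modularity, reports bivariate cross-checks for retained edges, and
    includes a sparse VAR(1) generator with trend and missing days so the
    whole pipeline can be validated on data with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    glmnet,
    igraph,
    jsonlite,
    Rcpp,
    e1071,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
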