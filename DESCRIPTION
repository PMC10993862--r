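Package: mgrtree
Title: Recursive Partitioning and Forests for Differential Item Functioning
    in Multidimensional Graded Response Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects differential item functioning (DIF) in multidimensional
    graded response and confirmatory factor analysis measurement models by
    model-based recursive partitioning over covariates. Trees are grown with
    limited-information maximum likelihood estimation and score-based parameter
    instability tests (maxLM, LMuo, maxLMo); terminal nodes of ordinal-response
    trees are re-estimated with a distribution-free weighted least squares fit
    to polychoric correlations, with chi-square and RMSEA fit indices. A
    random-split forest ensemble (no bagging) aggregates recurring well-fitting
    subgroups. Includes a synthetic-data factory for probit multistate item
    response (PIEG) data and its numeric CFA twin, with planted covariate-defined
    DIF subgroups.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    mvtnorm,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
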