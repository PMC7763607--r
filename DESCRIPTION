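Package: fragbb
Title: Fragment-Descriptor Neural Network Models of Blood-Brain Barrier
    Permeability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative structure-property modeling of blood-brain barrier
    permeability (LogBB) from substructural fragment descriptors. Enumerates
    linear path, ring and branch fragments of molecular graphs with a
    multi-level atom classification, builds integer occurrence-count
    descriptor matrices, selects relevant descriptors by stepwise partial
    least squares, univariate or recursive-elimination procedures, trains
    ensembles of SELU feed-forward regression networks under repeated double
    cross-validation, and applies them with a guarded prediction protocol
    (sanity range, ensemble agreement) plus gradient-based fragment
    contribution analysis for interpretation. Includes a synthetic compound
    generator with planted fragment effects so the whole workflow is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ChemmineR,
    ChemmineOB,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    mixOmics,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    e1071,
    glmnet,
    lhs,
    optparse,
    randomForest,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
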