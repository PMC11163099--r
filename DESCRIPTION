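Package: tiqspr
Title: Degree-Based Topological Indices and QSPR Regression for Molecular Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes eleven degree-based topological indices (first and second
    Zagreb, modified Zagreb, harmonic, hyper-Zagreb, forgotten, reciprocal
    Randic, Randic, sum-connectivity, geometric-arithmetic and atom-bond
    connectivity) of hydrogen-suppressed molecular graphs from degree-pair edge
    partitions, and fits univariate linear quantitative structure-property
    relationship (QSPR) models of physicochemical properties on each index with
    full inference statistics (correlation, F test, standard error of the
    estimate) and prediction tables. Ships the edge partitions and properties
    of five anticancer sulfonamide derivatives, a seeded generator of random
    degree-bounded molecular graphs with linear-model property values for
    validation, and a pipeline that emits every report table as CSV.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
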