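Package: facetransfer
Title: Cross-Property Transfer Analysis in Linear Discriminant Face Spaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how a linear face space trained on one facial
    property (identity, sex, race or facial expression) supports classification
    of another. Implements Eigenface principal-component preprocessing, multi-class
    Fisher discriminant subspaces with the class-count dimension cap and random
    orthogonal padding, a relabel-and-test transfer protocol scored with a
    pairwise delayed-match-to-sample estimator, within/between-class distance
    statistics (one-sided two-sample Kolmogorov-Smirnov tests, pooled two-sample
    t-tests), a seeded synthetic face-image generator emulating balanced
    identity/sex/race/viewpoint and identity/expression databases, and an
    orchestration layer that sweeps component and sample-size grids and renders
    the standard figures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
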