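Package: lhda
Title: Local Hyperplane Discriminant Analysis for Feature Weighting and
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simultaneous feature weighting and classification for
    high-dimensional labelled data such as gene-expression matrices.  A
    nonnegative per-feature weight vector is learned by gradient descent on a
    sigmoid-smoothed, l1-penalised leave-one-out margin error, where each
    sample's margin is the ratio of its weighted Manhattan distances to the
    local hyperplanes spanned by its nearest same-class and other-class
    neighbours.  Classification assigns a sample to the class whose local
    hyperplane is closest in the learned weighted metric (a feature-weighted
    hyperplane k-nearest-neighbour rule).  Includes a Fermat's-spiral
    benchmark generator, leave-one-out, stratified k-fold and nested
    leave-one-out cross-validation harnesses, a two-sample t-test prefilter
    for expression matrices, and delimited-table readers and writers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    quantreg,
    readr,
    rlang,
    stats,
    tibble,
    tidyselect,
    tools,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
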