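Package: gazelle
Title: Mountain Gazelle Optimization and Binary Wrapper Feature Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Swarm-intelligence optimization with the mountain gazelle
    optimizer (MGO) and an improved variant (IMGO) that adds chaotic-map
    population initialization, a nonlinear control factor, spiral
    perturbation, and neighborhood search around the incumbent best.  A
    sigmoid-transfer binary variant (BIMGO) performs wrapper feature
    selection on labeled tabular biomedical data with pluggable
    classifiers.  Includes the classical 23-function continuous benchmark
    suite, a synthetic labeled-data generator with known informative
    features, and a seeded experiment harness with Wilcoxon rank-sum
    comparisons and rank aggregation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    class,
    dplyr,
    e1071,
    foreign,
    generics,
    ggplot2,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
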