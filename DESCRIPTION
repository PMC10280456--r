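Package: veh
Title: Hybrid Variance / Extra-Trees / Harris Hawks Gene Selection for
    Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Three-stage hybrid feature-gene selection for high-dimensional
    expression matrices: a per-gene variance filter, an extremely randomized
    tree importance gate, and a binary Harris Hawks optimizer whose fitness
    combines k-nearest-neighbour cross-validation accuracy with a subset-size
    penalty. Includes the repeated stratified ten-fold evaluation protocol
    with decision tree, RBF support vector machine and l2-regularized
    logistic regression classifiers, macro-averaged precision/recall/F1,
    optimal-subset selection rules for stochastic runs, and a synthetic
    expression-data generator with known informative genes for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    class,
    e1071,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
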