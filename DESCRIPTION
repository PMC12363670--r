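Package: cellstateR
Title: Reference-Based Cell-State Annotation with Calibrated Certainty
    Scores and Shapley Explanations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Trains a multiclass linear max-margin classifier on a labeled
    single-cell RNA-seq reference atlas, reduces the gene space by
    Shapley-value-driven recursive feature elimination, calibrates per-class
    decision scores into probabilities, and annotates query datasets with
    cell-state labels, certainty scores binned into low/medium/high, and
    per-state explainable marker genes.  Includes a negative-binomial
    simulator for labeled atlases and query datasets with marker structure,
    library-size variation, batch shift, and novel states.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    data.table,
    jsonlite,
    methods,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    e1071,
    optparse,
    rhdf5,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
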