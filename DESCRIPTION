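Package: aammseq
Title: Abstraction Augmented Markov Models for Semi-Supervised Sequence Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits k-th order Markov models for biological sequence
    classification and their abstraction-augmented variants (AAMMs), in
    which the conditioning k-gram contexts are compressed into an
    abstraction hierarchy learned by greedy agglomerative merging under a
    weighted Jensen-Shannon divergence. The hierarchy is learned from
    labeled and unlabeled sequences together, so small labeled sets can
    borrow statistical strength from large unlabeled pools, as in
    semi-supervised protein subcellular localization prediction.
    Includes expectation-maximization and two-view co-training baselines
    for Markov models, stratified cross-validation with labeled-fraction
    subsampling, cross-validated paired t tests, a relative
    error-reduction statistic, and a ground-truth simulator for
    benchmarking every component without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
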