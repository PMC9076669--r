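Package: stressnet
Title: Consensus Bayesian Networks for Condition-Associated Gene Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A multi-step pipeline for identifying a small set of
    condition-associated genes from multiple RNA-seq studies: per-study
    empirical-Bayes differential-expression selection and cross-study
    intersection, quantile discretization into three expression levels,
    BDeu-scored Bayesian-network structure learning by simulated annealing,
    a grouped arc-weight ensemble consensus, and interpretation of the final
    network through the Markov blanket of the condition node and
    edge-betweenness community detection. Includes a synthetic-data module
    (ground-truth categorical Bayesian networks and paired negative-binomial
    count studies with planted condition-responsive genes) so the whole
    pipeline can be exercised end-to-end against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    limma,
    igraph
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
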