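Package: clustersig
Title: Significance Statistics for Approximate Gene Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the statistical significance of gene cluster predictions
    under the approximate common intervals model. Given genomes encoded as
    sequences of gene-family identifiers and a predicted cluster of genes, the
    package computes the probability of observing an equally or better
    conserved occurrence of the cluster under a null model of random gene
    order, using exact dynamic programming over missing and additional
    characters. Per-genome probabilities are combined across many genomes
    under a quorum constraint, and cluster p-values are corrected for multiple
    testing by false discovery rate control. Includes an exact brute-force
    reference-cluster finder, Monte-Carlo validation machinery with
    Agresti-Coull confidence intervals, and a Pareto genome simulator for
    generating realistic synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
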