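Package: msanet
Title: Gene Regulatory Network Inference and Assessment with Minimal Sets
    and Covariance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reverse engineering of gene regulatory networks from wild-type
    time-course expression data, and validation against knowledge-driven
    reference networks. Provides a mixed-graph network container (directed,
    undirected, absent and unknown pair states), rule-based construction of a
    gold standard network from an evidence table of perturbation, one-hybrid
    and genetic-interaction results, data-driven inference via discretization,
    the Minimal Sets Algorithm (exhaustive minimal hitting-set enumeration
    over state-transition difference sets) combined with median-thresholded
    covariance in either pipeline order, half-right-aware precision/recall and
    ROC assessment with signed distances from the random-guess diagonals,
    per-module feature subnetworks, graph statistics, and a synthetic data
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
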