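Package: lbnet
Title: Gene Regulatory Network Inference with Local Bayesian Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers directed gene regulatory networks from expression data by
    combining Gaussian mutual-information screening, k-nearest-neighbour
    decomposition of the thresholded co-expression network into small local
    subnetworks, exhaustive Bayesian-network structure search with a Gaussian
    BIC score inside each subnetwork, integration of the local structures into
    a candidate network, and conditional-mutual-information pruning of false
    positive edges, iterated to a stable directed network. Includes a
    linear-Gaussian structural-equation simulator for benchmark networks,
    confusion-matrix/ROC evaluation against gold-standard edge lists, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
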