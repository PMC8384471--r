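Package: mirwalk
Title: Degree-Biased Random Walk with Restart for miRNA-Disease Ranking
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Ranks candidate microRNAs for a query disease by a degree-biased
    random walk with restart on a multilayer heterogeneous network. The network
    couples a disease layer (integrated semantic and Gaussian interaction
    profile kernel similarity), a miRNA layer (functional plus kernel
    similarity), and the bipartite layer of experimentally verified
    miRNA-disease associations. Includes ontology-based disease semantic
    similarity (two models), Gaussian interaction profile kernels, a local
    leave-one-out cross-validation harness with rank-based ROC/AUC, a seeded
    synthetic data generator with planted cluster structure, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
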