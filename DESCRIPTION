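Package: dellanet
Title: Comparative Analysis of DELLA-Associated Gene Co-Expression Networks
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Infers thresholded gene co-expression networks from FPKM-style
    expression matrices, builds DELLA-interactor-seeded "Neighbors" and
    "Orthologs" subnetworks across species via OrthoMCL-style ortholog
    groups, and quantifies cross-species differences in network topology,
    neighborhood and link conservation (Fisher exact tests in ortholog-group
    space), shortest-path-length distributions, and 3/4-node undirected
    motif enrichment. Includes a synthetic multi-species data generator with
    planted co-expression modules so the whole pipeline is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
biocViews: NetworkInference, GraphAndNetwork, GeneExpression, Network
RoxygenNote: 7.3.3
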