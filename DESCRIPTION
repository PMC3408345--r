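Package: dualnets
Title: Dual Co-Expression and Interactome Network Module Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for dual-network analysis of paired
    pre/post treatment expression studies: mutual-information co-expression
    network inference with kernel-width and threshold calibration,
    data-processing-inequality pruning and bootstrap consensus; MCODE-style
    dense-module detection; beta-uniform-mixture scoring of interaction-network
    nodes with exact and heuristic maximum-weight connected subgraph search;
    hypergeometric over-representation with ontology-conditional testing and
    pathway filtering; and a permutation test for pathways shared between
    modules found in the two networks. Includes seeded synthetic-data
    generators emulating a paired two-arm microarray design so the entire
    workflow is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    limma,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
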