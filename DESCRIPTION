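Package: ontofuse
Title: LCA-Preserving Integration of Hierarchical Ontologies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Merges two or more hierarchical (tree-structured) ontologies
    into a single integrated tree that preserves every source ontology's
    lowest-common-ancestor relationships while maximising the total
    closeness (cohesion) of merged term pairs. Provides an exact dynamic
    programme over subtree pairs with optimal weighted bipartite matching,
    a 1/2-approximation via greedy maximal matching, a depth-regularised
    top-down heuristic, and three strategies for integrating many
    ontologies at once, including a contraction scheme with a 1/(k-1)
    approximation guarantee. Includes a synthetic benchmark generator,
    brute-force oracles for validation, and readers/writers for edge-list,
    hierarchy-path, closeness-triple and merged-ontology formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
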