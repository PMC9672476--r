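Package: winnr
Title: Weighted Interaction Network Gene Prioritization and Expansion
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Scores and ranks seed genes in weighted, optionally directed,
    gene-gene interaction networks with a damped random-walk propagation of
    confidence-weighted initial scores; attaches statistical significance to
    each gene's converged score via topology-preserving network randomization
    (degree-preserving, modularity-preserving, total rewiring, and edge
    perturbation null models); and grows the network one statistically
    justified candidate gene at a time using dual hypergeometric enrichment
    filters and a confidence-weighted expansion score. Includes evaluation
    utilities (retrieval metrics, breadth-first pathway layer assignment with
    cycle collapse, classical centrality baselines, pathway-level assignment
    and rank-bin correlation) and deterministic synthetic-network generators
    for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
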