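Package: egdv
Title: Graphlet-Based Edge Clustering of Protein Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Edge graphlet degree vectors (edge-GDV) and a weighted
    edge-GDV-similarity measure for comparing the extended topological
    neighbourhoods of edges in undirected networks, together with the
    surrounding workflow: enumeration of all 2-5-node graphlets with their
    node and edge automorphism orbits and orbit dependency weights, exact
    per-node and per-edge orbit counting, the shared-neighbourhood (edge-SN)
    similarity, single-linkage and k-medoids clustering of nodes or edges,
    partition-density and partition-quality evaluation (cluster coverage,
    overlap coverage, cluster quality, overlap quality), and hypergeometric
    cluster-enrichment prediction of pathogen-interacting proteins with
    leave-one-out cross-validation and randomised baselines. Includes
    seed-deterministic synthetic network generators (planted edge
    communities, planted annotations, planted pathogen-interaction modules)
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
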