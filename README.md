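# egdv — graphlet-based edge clustering of protein interaction networks

Proteins carry out their functions in overlapping modules, but classical
network clustering partitions *nodes* into disjoint groups and loses the
overlap. Clustering *edges* keeps it: a protein belongs to every module
that one of its interactions belongs to. `egdv` implements a sensitive,
adjacency-free measure of edge similarity — the **edge graphlet degree
vector (edge-GDV)** and **edge-GDV-similarity** — and the workflow around
it: clustering of edges or nodes, partition-quality evaluation, and
hypergeometric cluster-enrichment prediction of pathogen-interacting (PI)
proteins, i.e. candidate drug targets.

## The measure

A graphlet is a small connected induced subgraph; on 2–5 nodes there are
30 of them, carrying 73 node orbits and 69 edge orbits (automorphism
equivalence classes of nodes and edges). The edge-GDV of an edge counts,
for each of the 68 edge orbits of the 3–5-node graphlets, how many induced
subgraphs touch the edge at that orbit — a fingerprint of the edge's
up-to-4-deep neighbourhood. Two edge-GDVs are compared per orbit,

    D_i(e,f) = w_i · |log(e_i+1) − log(f_i+1)| / log(max(e_i,f_i)+2),

with weights `w_i = 1 − log(o_i)/log(68)` discounting orbits that are
implied by `o_i` other orbits, and combined as
`S(e,f) = 1 − Σ D_i / Σ w_i ∈ (0,1]`. Unlike shared-neighbour link
similarity, `S` is defined for *any* edge pair, adjacent or not.

On top of that: single-linkage hierarchical clustering with
partition-density-guided level selection, seeded k-medoids, the
cluster-coverage / overlap-coverage / cluster-quality / overlap-quality
partition score, and leave-one-out cross-validated prediction of new
protein–pathogen associations with a size-matched random baseline.

## Worked example

A planted-partition network (4 modules × 8 proteins) with 4 pathogens
whose interactors concentrate in one module each:

```r
library(egdv)

graphlet_atlas()
#> Graphlet atlas: 30 graphlets (2-5 nodes), 73 node orbits, 69 edge orbits

p4 <- igraph::make_graph(~ a-b, b-c, c-d)
count_edge_gdv(p4)[, c("o1", "o3", "o4")]
#>     o1 o3 o4
#> a|b  1  1  0
#> b|c  2  0  1
#> c|d  1  1  0

g    <- make_graph_fixture("planted_partition", blocks = 4, block_size = 8,
                           p_within = 0.8, p_between = 0.02, seed = 1)
pmap <- make_pathogen_map(g, n_pathogens = 4, within_fraction = 0.9,
                          n_interactors = 6, seed = 201)

eg   <- count_edge_gdv(g)                      # counted on the full graph
filt <- degree_filter(g, 3)                    # cluster the dense core only
S    <- edge_gdv_similarity_matrix(eg[intersect(rownames(eg), filt$edges), ],
                                   graph = g, adjacent_only = TRUE)
part <- select_partition(single_linkage(S), "max_density")
part
#> Partition of 90 edges into 7 clusters
partition_density(part)$D
#> [1] 0.745

elig <- eligible_universe(g, pmap, min_degree = 3)
pr   <- loocv_pr_curve(part, elig)
pr[pr$k == 66, c("k", "precision", "recall", "f_score")]
#>     k precision    recall   f_score
#> 67 66         1 0.8333333 0.9090909
base <- random_baseline(part, elig, runs = 20, seed = 500)
base$mean_f[base$k == 66]
#> [1] 0
```

The middle edge of a 4-path touches two 3-node paths (orbit 1) and sits at
the 4-path's middle orbit (orbit 4), while an outer edge sits at orbit 3 —
the counts above are those fingerprints. On the planted network, the
maximum-density cut of the adjacent-edge dendrogram recovers the modules,
and hiding each known association one at a time still recovers 83% of
them at the 66% enrichment threshold with perfect precision, while
size-matched random clusters recover none. `predict_new(part, elig,
k = 66)` would list yet-unassociated proteins of enriched clusters — here
the planted modules are fully associated, so nothing new remains.

A command-line front end with the same steps (`atlas`, `gdv`,
`similarity`, `cluster`, `quality`, `enrich`, `baseline`, `predict`,
`simulate`, `run`) is installed under `inst/cli/egdv.R`.

## Layout

- `R/` — atlas and orbit weights, GDV counting, similarities, clustering,
  partition quality, enrichment/LOOCV, synthetic fixtures, IO and the
  pipeline runner.
- `tests/testthat/` — unit and property tests per module, an independent
  brute-force counting oracle, and the acceptance suite.
- `vignettes/edge-graphlet-clustering.Rmd` — the methods vignette: model,
  assumptions, parameter choices, numerical conventions, limitations.
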