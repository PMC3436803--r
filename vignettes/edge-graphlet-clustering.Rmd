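---
title: "Edge graphlet degree vectors and graphlet-based edge clustering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Edge graphlet degree vectors and graphlet-based edge clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(egdv)
```

## Why cluster edges, and why by graphlets

Proteins are multifunctional: a node in a protein–protein interaction
(PPI) network typically participates in several functional modules at
once.  Disjoint *node* clustering cannot express that overlap, but *edge*
clustering can — a node inherits membership in every cluster that contains
one of its edges, so overlapping node communities fall out of a disjoint
edge partition for free.

The earlier generation of link clustering grouped *adjacent* edges whose
non-shared endpoints have similar neighbourhoods.  That measure only sees
one step of topology, and it only compares edges that already touch.  Most
pairs of host proteins that bind the same pathogen are *not* adjacent in
the PPI network, so a similarity that can compare arbitrary edge pairs by
the shape of their wider surroundings is the natural generalisation.  This
package provides that measure — the **edge graphlet degree vector
(edge-GDV)** and its weighted **edge-GDV-similarity** — together with the
clustering, partition-evaluation and enrichment-prediction workflow built
on top of it.

## Graphlets, orbits and the atlas

A *graphlet* is a small connected induced subgraph.  On 2–5 nodes there
are exactly 30 of them, and `graphlet_atlas()` enumerates all of them from
scratch: every labelled simple graph on up to 5 nodes is generated, tested
for connectivity, and reduced to a canonical representative; automorphism
groups are found by exhaustive permutation (at most 120 per graph, so the
exhaustive route is exact and still fast).

Within one graphlet, two nodes are interchangeable if some automorphism
maps one to the other; the equivalence classes are the *node orbits*, and
the same construction on edges yields the *edge orbits*.  Across the atlas
there are 73 node orbits and 69 edge orbits; the single edge orbit of the
2-node graphlet is set aside for edge counting (every edge trivially
touches itself), leaving the 68 informative edge orbits of the 3–5-node
graphlets.

```{r atlas}
atlas <- graphlet_atlas()
atlas
```

Orbit numbering is a convention, not substance — all downstream
similarities depend only on the dependency structure of the orbits, never
on their labels.  We pin the conventional anchors (the 2-node edge is
graphlet 0 and edge orbit 0; the 3-node path's edges are edge orbit 1; the
triangle's are orbit 2; the 4-node path's outer and middle edges are
orbits 3 and 4) by ordering graphlets by node count, then edge count, then
ascending degree sequence, and numbering orbits within a graphlet from the
largest orbit down, breaking ties by smallest member.  The full mapping is
available as a reference table from `atlas_table()`.

## Orbit dependencies and weights

Orbit counts are not independent.  Every graphlet that touches an edge at
the triangle orbit also contains, inside itself, copies of smaller orbits
through the same edge, so differences at deeply nested orbits echo through
all the orbits that contain them.  To keep the similarity from
over-counting this redundancy, each edge orbit \(i\) gets a weight

\[ w_i = 1 - \frac{\log o_i}{\log 68}, \]

where \(o_i\) counts the orbits that affect orbit \(i\), including itself.
We formalise "affects" as **induced** occurrence through the focal edge:
orbit \(j\) affects orbit \(i\) when the graphlet housing \(j\) appears as
an induced subgraph of the graphlet housing \(i\) under a mapping that
carries an edge of orbit \(j\) onto the focal edge.  The induced reading
is the right one on three counts: every network copy of orbit \(i\)'s
graphlet then *necessarily* contributes to orbit \(j\)'s count of the
focal edge, so the dependency is real rather than incidental; the triangle
orbit ends up affecting exactly the orbits whose focal edge lies inside an
induced triangle (the classical worked example); and all weights stay
strictly positive — under a non-induced reading the complete graphlet's
edge orbit would be "affected" by all 68 orbits and receive weight exactly
0, which would silently delete that orbit from the similarity and break
the property that similarity 1 occurs only between identical vectors.

Node orbits get the same treatment with normaliser \(\log 73\); the
degree orbit depends only on itself and keeps weight 1.

```{r weights}
w <- edge_orbit_weights()
range(w$w)
sum(w$w == 1)   # fully independent orbits (3-node path, triangle)
```

## Counting: exact enumeration with lookup-table classification

`count_edge_gdv()` and `count_node_gdv()` count, for every edge (node),
the number of connected induced subgraphs on up to 5 nodes touching it at
each orbit.  Counting is exact, not sampled: connected induced subgraphs
are enumerated exactly once each by recursive extension with exclusive
neighbourhoods, and each subgraph is classified in constant time through
precomputed lookup tables that map a labelled adjacency code directly to
the global orbit of every node and edge position.  Each enumerated subset
therefore increments exactly one orbit count of each of its nodes and
edges — which yields sharp conservation identities (the degree column sums
to twice the edge count; the triangle orbit column sums to three times the
triangle count) that the test suite checks, alongside equality with an
independent brute-force oracle that iterates all node subsets and
classifies by VF2 isomorphism.

```{r count}
p4 <- igraph::make_graph(~ a - b, b - c, c - d)
count_edge_gdv(p4)[, c("o1", "o3", "o4")]
```

## The similarity

For edges \(e, f\) with counts \(e_i, f_i\) at orbit \(i\):

\[ D_i(e,f) = w_i \frac{\lvert \log(e_i+1) - \log(f_i+1) \rvert}
                       {\log(\max(e_i, f_i) + 2)},
\qquad
D(e,f) = \frac{\sum_i D_i(e,f)}{\sum_i w_i},
\qquad
S(e,f) = 1 - D(e,f). \]

The logs damp order-of-magnitude count differences, the denominator makes
each component a *relative* difference bounded strictly below \(w_i\), and
the +1/+2 constants keep everything finite.  Normalising the total
distance by \(\sum_i w_i\) mirrors the node-GDV-similarity construction
this measure generalises and guarantees \(S \in (0,1]\) with \(S = 1\)
exactly for identical vectors.  (Plain Euclidean distance on the raw
counts would be dominated by the largest, most redundant orbits — that is
precisely what the weights and logs are for.)

Two scopes are exposed: the unrestricted variant compares *all* edge
pairs, and the adjacent-only variant assigns non-adjacent pairs similarity
0 (the infimum of the scale) so single-linkage clustering can never merge
through them before exhausting adjacent pairs.  The shared-neighbourhood
measure `edge_sn_similarity()` — the Jaccard coefficient of the inclusive
neighbourhoods of the non-shared endpoints — is included both as the
baseline it historically is and as a coverage yardstick for partition
selection.

## Clustering

**Single-linkage hierarchical clustering** (`single_linkage()`) runs on
the distance \(1 - S\) through `stats::hclust`; merge similarities are
non-increasing by construction.  `cut_dendrogram(d, K)` undoes the last
\(K-1\) merges, with one deliberate wrinkle: tied merge levels are treated
as a single level.  When the requested \(K\) falls inside a block of
equal-similarity merges, the whole block stays merged and the nearest
achievable \(K' \le K\) is returned (and recorded).  Cutting is therefore
a function of the similarity level, never of the arbitrary order in which
tied merges happen to be listed.

**Partition density.**  An edge cluster with \(m_C\) edges spanning
\(n_C\) nodes has density
\(D_C = [m_C - (n_C-1)] / [n_C(n_C-1)/2 - (n_C-1)]\) — the fraction of
possible edges beyond a spanning tree that are realised — and the overall
partition density is the edge-weighted mean
\(D = \tfrac{2}{M}\sum_C m_C\,[m_C-(n_C-1)]/[(n_C-2)(n_C-1)]\).
A single-edge cluster (\(n_C = 2\)) makes the formula degenerate and is
scored 0, the established convention for such "trivial" clusters.  A
triangle as its own cluster gives \(D_C = D = 1\), which the tests pin to
machine precision.

**Partition selection** (`select_partition()`) scans all achievable cut
levels and optimises one of three objectives: maximum density; maximum
density under a cluster-coverage cap (coverage correlates strongly and
negatively with the per-cluster quality measures, so an uncapped density
optimum can win by covering almost nothing); or best overall partition
quality.  For large dendrograms a subset of levels can be supplied.

**k-medoids** (`k_medoids()`) alternates nearest-medoid assignment with
medoid recomputation on a precomputed \(1 - S\) distance.  Initialisation
is a uniform random sample of K distinct items under a *required* seed,
ties break towards the smallest index, and iterations cap at 300 — the
algorithm is known not to stabilise for unfavourable K on large networks,
so reproducibility has to be engineered rather than assumed.  Both steps
are non-increasing in total cost, which the tests assert per iteration.

**Degree filter.**  Clustering and all enrichment analyses consider only
nodes with more than three interaction partners (and edges between them);
poorly connected proteins are disproportionately noise.  GDVs are always
computed on the *full* network first — the filter restricts what is
clustered, not what topology is seen.

Defaults follow the workflow this package implements: \(K = 1250\) for
hierarchical and \(K = 1000\) for k-medoids clustering at interactome
scale (`egdv_config()`), both to be scaled down for small inputs.

## Partition quality

Four measures, combined by normalising each across the compared methods
(best method = 1) and summing, for a maximum of 4:

* **CC**, cluster coverage: fraction of nodes in at least one non-trivial
  cluster (≥ 3 induced nodes).
* **OC**, overlap coverage: mean number of non-trivial clusters per node.
* **CQ**, cluster quality: mean pairwise annotation similarity within
  clusters over the mean across the network.  The pairwise similarity is
  injectable; the default is the Jaccard index of term sets, which needs
  no ontology structure.  Both averages are restricted to annotated nodes,
  and a pair counts once per shared cluster.
* **OQ**, overlap quality: mutual information (plug-in estimate, base 2,
  unbinned counts) between per-node term counts and per-node non-trivial
  cluster counts.

## Enrichment and prediction of pathogen-interacting proteins

The prediction logic scores each (cluster, pathogen) pair by the
hypergeometric upper tail: among \(N\) eligible pathogen-interacting
proteins, \(P\) interact with the pathogen, the cluster holds \(C\) of the
universe, \(p\) of which interact — enrichment \(p/C\), significance
\(\Pr(X \ge p)\) at raw \(\alpha = 0.05\) (no multiple-testing correction;
the downstream cross-validation is the error control here).  Eligibility:
degrees above three, and pathogens with at least two qualifying
interactors — with one interactor a pathogen could never be predicted for
anyone else and would only depress recall.  A cluster needs \(p \ge 2\) to
witness enrichment at all.

**Leave-one-out cross-validation** (`loocv_pr_curve()`): for every protein
of a significantly enriched cluster, its association with the pathogen is
hidden, the cluster's enrichment *and significance* are recomputed on the
remaining data (hiding decrements both the cluster count \(p\) and the
pathogen total \(P\); reusing full-data significance is available as a
switch, but full recomputation is the conservative default), and the
association is predicted when the enrichment strictly exceeds the
threshold \(k\), swept from 0% to 100% in 1% steps.  Predictions aggregate
per (protein, pathogen) — a pair is predicted if any of the protein's
clusters qualifies — and precision, recall and
\(F = 2PR/(P+R)\) (0 when both vanish) are tallied against the hidden
truth.  Recall is non-increasing in \(k\) and the number of tested known
associations is conserved across thresholds, both assert-checked.

The **random baseline** (`random_baseline()`) reassigns nodes to clusters
of the data sizes, uniformly and seed-deterministically, and averages F
per threshold over the runs; planted or real signal must clear this bar.
`predict_new()` finally emits, at a chosen working point (default
\(k = 66\%\), the highest threshold that costs little F), all
yet-unassociated proteins of qualifying clusters, and
`merge_predictions()` overlays prediction sets from several clustering
strategies, recording per-prediction provenance — agreement of multiple
strategies marks higher-confidence candidates.

## What the synthetic generator emulates — and what it does not

`make_graph_fixture()` provides the study conditions for all tests: a
planted-partition graph of 4 blocks × 8 nodes with within-block edge
probability 0.8 and between-block probability 0.02 — dense, clearly
separated modules at a size where the whole pipeline runs in seconds.
`make_annotations()` gives each block a dominant term at purity 0.9 (plus
occasional extra terms so term counts vary), and `make_pathogen_map()`
gives each of 4 pathogens 6 interactors, 90% drawn from a home block —
a pathogen attacking one module, with a little off-module noise.  Those
values are the fixture defaults used throughout the test suite; the
acceptance checks run the full pipeline on graphs of this size (≈ 32
nodes, ≈ 100 edges) and the counting oracle on 50 random graphs of 8–15
nodes.

Two honest caveats.  First, planted blocks generated identically are
*topologically interchangeable*: the unrestricted edge-GDV-similarity
correctly reports edges of different blocks as similar, because their
extended neighbourhoods really are alike.  Recovering planted *membership*
therefore uses the adjacent-only variant with maximum-density selection,
which is also the configuration whose recovery the acceptance suite
checks; the unrestricted variant's distinctive ability — grouping
topologically alike but distant edges — is exactly what a block-recovery
score cannot measure.  Second, the generator makes no attempt at
power-law degrees, assay-specific false positives or incomplete sampling;
passing tests demonstrate correctness of the machinery on clean planted
structure, not performance claims about real interactomes.

## Numerical and degenerate-input choices

* Similarity values are dense doubles; matrices are fine at test scale,
  and the pairwise kernel streams row blocks to bound memory.
* Self-loops and duplicate edges are dropped on input with a counted
  warning.
* The empty graph yields empty GDV matrices; a single-item dendrogram is
  a degenerate single-leaf tree; `K` out of range is an error.
* k-medoids requires its seed; hierarchical clustering is deterministic
  throughout (hclust's ordering plus the tie-block cut rule).
* CQ is reported as `NA` with a message when no annotated pair shares a
  cluster; a quality measure whose cross-method maximum is 0 contributes
  0 to every method.

## Known limitations

Exact counting enumerates every connected ≤ 5-node induced subgraph, so
runtime grows with dense neighbourhoods (roughly the number of such
subgraphs); interactome-scale networks are feasible but take hours in
pure R, and orbit counting beyond 5 nodes is out of scope.  The CQ
default (Jaccard over term sets) is deliberately structure-free;
information-content semantic similarities can be injected but no ontology
parsing is provided.  Single-linkage chaining can bridge planted modules
through sparse inter-module edges at low similarity levels — the
density-guided selection exists precisely to pick the level where that
has not yet happened.
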