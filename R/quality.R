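# Partition-quality measures: cluster coverage (CC), overlap coverage
# (OC), cluster quality (CQ) and overlap quality (OQ), plus cross-method
# normalisation into the overall score.  A "non-trivial" cluster is one
# whose induced node set has at least three nodes; for edge partitions
# node membership is the overlapping membership induced by incident edges.

# Per-node count of non-trivial clusters containing it, over a universe.
.nontrivial_membership <- function(partition, node_universe) {
  sets <- partition_node_sets(partition)
  sets <- sets[vapply(sets, length, 0L) >= 3L]
  counts <- stats::setNames(integer(length(node_universe)), node_universe)
  for (s in sets) {
    s <- intersect(s, node_universe)
    counts[s] <- counts[s] + 1L
  }
  counts
}

#' Cluster coverage (CC)
#'
#' Fraction of the node universe belonging to at least one non-trivial
#' cluster (three or more induced nodes).
#'
#' @param partition An `egdv_partition`.
#' @param node_universe Character vector of nodes over which coverage is
#'   measured (for a filtered network, the nodes that survived the degree
#'   filter).
#' @return Fraction in `[0, 1]`.
#' @export
cluster_coverage <- function(partition, node_universe) {
  if (!length(node_universe)) stop("empty node universe")
  mean(.nontrivial_membership(partition, node_universe) >= 1L)
}

#' Overlap coverage (OC)
#'
#' Average number of non-trivial clusters that a node belongs to.  For
#' disjoint node partitions this is at most the cluster coverage; edge
#' partitions can exceed 1 through overlapping induced memberships.
#'
#' @inheritParams cluster_coverage
#' @return Non-negative mean membership count.
#' @export
overlap_coverage <- function(partition, node_universe) {
  if (!length(node_universe)) stop("empty node universe")
  mean(.nontrivial_membership(partition, node_universe))
}

#' Annotation-set Jaccard similarity
#'
#' Default pairwise similarity between two term sets for [cluster_quality()].
#' @param a,b Character vectors of term identifiers.
#' @return Jaccard coefficient in `[0, 1]`.
#' @export
annotation_jaccard <- function(a, b) {
  length(intersect(a, b)) / length(union(a, b))
}

#' Cluster quality (CQ)
#'
#' Ratio of the average pairwise annotation similarity over node pairs
#' sharing a cluster to the average over all node pairs in the network.
#' Pairs are counted once per shared cluster membership, and both averages
#' are restricted to annotated nodes (pairs with no annotations have no
#' defined similarity).  CQ > 1 means clusters group functionally similar
#' nodes better than chance.
#'
#' @param partition An `egdv_partition`.
#' @param annotations Named list: node -> character vector of term ids
#'   (see [read_annotations()] / [make_annotations()]).
#' @param pair_similarity Symmetric function of two term sets; defaults to
#'   [annotation_jaccard()].  Semantic similarities can be injected here.
#' @param node_universe Nodes forming "the network" for the denominator;
#'   defaults to the partition's induced node set.
#' @return The CQ ratio, or `NA` (with a message) if no annotated pair
#'   shares a cluster.
#' @export
cluster_quality <- function(partition, annotations,
                            pair_similarity = annotation_jaccard,
                            node_universe = NULL) {
  if (is.null(node_universe)) node_universe <- .default_universe(partition)
  annotated <- intersect(node_universe, names(annotations))
  annotated <- annotated[vapply(annotations[annotated], length, 0L) > 0L]
  if (length(annotated) < 2L) {
    message("fewer than two annotated nodes; CQ undefined")
    return(NA_real_)
  }
  sim_cache <- function(u, v) pair_similarity(annotations[[u]], annotations[[v]])
  # denominator: all annotated pairs in the network
  all_sims <- utils::combn(annotated, 2L,
                           function(p) sim_cache(p[1L], p[2L]))
  intra <- numeric(0)
  for (s in partition_node_sets(partition)) {
    s <- intersect(s, annotated)
    if (length(s) < 2L) next
    intra <- c(intra, utils::combn(s, 2L, function(p) sim_cache(p[1L], p[2L])))
  }
  if (!length(intra)) {
    message("no annotated intra-cluster pairs; CQ undefined")
    return(NA_real_)
  }
  mean(intra) / mean(all_sims)
}

#' Overlap quality (OQ)
#'
#' Mutual information, in bits, between the number of annotation terms a
#' node has and the number of non-trivial clusters it belongs to, over the
#' empirical joint distribution on the node universe.  High OQ means the
#' cluster-overlap structure tracks multifunctionality.  Counts are used
#' unbinned; degenerate (constant) variables give 0.
#'
#' @inheritParams cluster_quality
#' @param node_universe Nodes over which the joint distribution is taken.
#' @return Mutual information in bits (non-negative).
#' @export
overlap_quality <- function(partition, annotations, node_universe = NULL) {
  if (is.null(node_universe)) node_universe <- .default_universe(partition)
  x <- vapply(node_universe, function(v)
    length(annotations[[v]] %||% character(0)), 0L)
  y <- .nontrivial_membership(partition, node_universe)
  joint <- table(x, y) / length(node_universe)
  px <- rowSums(joint); py <- colSums(joint)
  mi <- 0
  for (i in seq_along(px)) for (j in seq_along(py)) {
    p <- joint[i, j]
    if (p > 0) mi <- mi + p * log2(p / (px[i] * py[j]))
  }
  max(mi, 0)
}

#' All four quality measures for one partition
#'
#' @inheritParams cluster_quality
#' @return List with `cc`, `oc`, `cq`, `oq`.
#' @export
quality_report <- function(partition, annotations, node_universe = NULL,
                           pair_similarity = annotation_jaccard) {
  if (is.null(node_universe)) node_universe <- .default_universe(partition)
  list(cc = cluster_coverage(partition, node_universe),
       oc = overlap_coverage(partition, node_universe),
       cq = suppressMessages(cluster_quality(partition, annotations,
                                             pair_similarity, node_universe)),
       oq = overlap_quality(partition, annotations, node_universe))
}

#' Normalise quality measures across methods and sum into overall scores
#'
#' Raw CC/OC/CQ/OQ values live on different scales, so each measure is
#' divided by its maximum across the compared partitions (the best method
#' scores 1 on each measure) and the overall partition quality is the sum
#' of the four normalised values — at most 4.  A measure whose maximum is
#' 0 (or undefined everywhere) contributes 0 to every method.
#'
#' @param reports List of at least two reports from [quality_report()].
#' @return The reports, each augmented with `normalized` (named vector) and
#'   `overall`.
#' @export
normalize_and_score <- function(reports) {
  if (length(reports) < 2L) stop("need at least two reports to normalise")
  measures <- c("cc", "oc", "cq", "oq")
  vals <- sapply(measures, function(m)
    vapply(reports, function(r) r[[m]] %||% NA_real_, 0))
  vals <- matrix(vals, nrow = length(reports),
                 dimnames = list(NULL, measures))
  mx <- apply(vals, 2L, function(v) {
    v <- v[is.finite(v)]
    if (!length(v)) 0 else max(v)
  })
  lapply(seq_along(reports), function(i) {
    r <- reports[[i]]
    norm <- vapply(measures, function(m) {
      v <- vals[i, m]
      if (!is.finite(v) || mx[m] == 0) 0 else v / mx[m]
    }, 0)
    r$normalized <- norm
    r$overall <- sum(norm)
    r
  })
}
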