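# Clustering of nodes or edges by a precomputed similarity: single-linkage
# hierarchical clustering with density-guided dendrogram cutting, and
# k-medoids with a fixed K.

# Run code with a fixed RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Single-linkage hierarchical clustering from a similarity matrix
#'
#' Agglomerates items by iteratively merging the pair of clusters with the
#' highest cross-pair similarity (equivalently, single linkage on the
#' distance 1 - S).  Pairs absent from the matrix should be encoded as
#' similarity 0.  The result records the merge order and the similarity at
#' each merge; merge similarities are non-increasing.
#'
#' @param similarity Symmetric similarity matrix with item names on both
#'   dimensions (e.g. from [edge_gdv_similarity_matrix()]).
#' @return An `egdv_dendrogram`: list with `items`, the underlying
#'   [stats::hclust] tree, and `merge_sim` (similarity at each merge).
#' @export
single_linkage <- function(similarity) {
  items <- rownames(similarity)
  if (is.null(items)) stop("similarity matrix must have item names")
  n <- length(items)
  if (n < 2L) {
    out <- list(items = items, hclust = NULL, merge_sim = numeric(0))
    class(out) <- "egdv_dendrogram"
    return(out)
  }
  hc <- stats::hclust(stats::as.dist(1 - similarity), method = "single")
  out <- list(items = items, hclust = hc, merge_sim = 1 - hc$height)
  class(out) <- "egdv_dendrogram"
  out
}

#' @export
print.egdv_dendrogram <- function(x, ...) {
  cat(sprintf("Single-linkage dendrogram over %d items (%d merges)\n",
              length(x$items), length(x$merge_sim)))
  invisible(x)
}

#' Cut a dendrogram into K clusters
#'
#' Undoes the last K-1 merges.  Tied merge levels are treated as a single
#' level: when the requested K falls inside a block of equal-similarity
#' merges the whole block is kept together, and the nearest achievable
#' partition with K' <= K clusters is returned (recorded in the result).
#'
#' @param dendrogram An `egdv_dendrogram` from [single_linkage()].
#' @param K Requested number of clusters, between 1 and the number of items.
#' @return An `egdv_partition`: list with named integer `assignment`
#'   (item -> cluster id), `K` (achieved), `requested_K`, `items`.
#' @export
cut_dendrogram <- function(dendrogram, K) {
  items <- dendrogram$items
  n <- length(items)
  if (n == 1L) {
    if (K != 1L) stop("K out of range")
    return(.make_partition(stats::setNames(1L, items), K))
  }
  if (K < 1L || K > n) stop("K out of range")
  h <- dendrogram$hclust$height
  m <- n - K
  while (m > 0L && m < n - 1L &&
         isTRUE(all.equal(h[m + 1L], h[m])) ) m <- m + 1L
  assignment <- .apply_merges(dendrogram$hclust$merge, m, n)
  names(assignment) <- items
  .make_partition(assignment, K)
}

# Apply the first m merges of an hclust merge matrix; returns integer
# cluster ids 1..(n - m), numbered by first appearance in item order.
.apply_merges <- function(merge, m, n) {
  comp <- seq_len(n)
  find <- function(x) { while (comp[x] != x) x <- comp[x]; x }
  cl_of_merge <- integer(m)
  for (s in seq_len(m)) {
    a <- merge[s, 1L]; b <- merge[s, 2L]
    ra <- if (a < 0L) find(-a) else find(cl_of_merge[a])
    rb <- if (b < 0L) find(-b) else find(cl_of_merge[b])
    comp[max(ra, rb)] <- min(ra, rb)
    cl_of_merge[s] <- min(ra, rb)
  }
  roots <- vapply(seq_len(n), find, 0L)
  as.integer(factor(roots, levels = unique(roots)))
}

.make_partition <- function(assignment, requested_K = NULL,
                            kind = NULL) {
  if (is.null(kind))
    kind <- if (all(grepl("|", names(assignment), fixed = TRUE)))
      "edge" else "node"
  out <- list(assignment = assignment,
              K = length(unique(assignment)),
              requested_K = requested_K %||% length(unique(assignment)),
              items = names(assignment),
              kind = kind)
  class(out) <- "egdv_partition"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.egdv_partition <- function(x, ...) {
  cat(sprintf("Partition of %d %ss into %d clusters\n",
              length(x$items), x$kind, x$K))
  invisible(x)
}

#' Node sets induced by a partition
#'
#' For a node partition, each cluster's members; for an edge partition, the
#' union of each cluster's edge endpoints — the overlapping node
#' communities that edge clustering yields (a node belongs to the induced
#' set of every cluster that contains one of its edges).
#'
#' @param partition An `egdv_partition`.
#' @return Named list of character vectors, one per cluster.
#' @export
partition_node_sets <- function(partition) {
  if (!is.null(partition$node_sets)) return(partition$node_sets)
  cl <- split(partition$items, partition$assignment)
  if (partition$kind == "edge")
    cl <- lapply(cl, function(e) unique(as.vector(.edge_endpoints(e))))
  cl
}

#' Partition density of an edge partition
#'
#' Scores how densely each cluster's edges fill the range of its node set.
#' A cluster with \eqn{m_C} edges over \eqn{n_C} nodes has density
#' \deqn{D_C = \frac{m_C - (n_C - 1)}{n_C(n_C-1)/2 - (n_C - 1)},}
#' the fraction of possible edges beyond a spanning tree that are present
#' (0 for a tree, 1 for a clique; defined as 0 for a single-edge cluster,
#' where the formula degenerates).  The overall partition density is the
#' edge-weighted mean
#' \deqn{D = \frac{2}{M} \sum_C m_C \frac{m_C - (n_C-1)}{(n_C-2)(n_C-1)},}
#' with M the number of clustered edges.
#'
#' @param partition An edge `egdv_partition`.
#' @param graph Optional; unused for the computation (the cluster edge keys
#'   carry their endpoints) but accepted for interface symmetry.
#' @return List with overall `D` and a data frame `per_cluster`
#'   (`cluster`, `m`, `n`, `D_C`).
#' @examples
#' tri <- igraph::make_graph(~ a - b, b - c, c - a)
#' p <- single_cluster_partition(edge_keys(tri))
#' partition_density(p)$D   # 1
#' @export
partition_density <- function(partition, graph = NULL) {
  if (partition$kind != "edge")
    stop("partition density is defined for edge partitions")
  cl <- split(partition$items, partition$assignment)
  m <- vapply(cl, length, 0L)
  n <- vapply(cl, function(e)
    length(unique(as.vector(.edge_endpoints(e)))), 0L)
  dc <- ifelse(n <= 2L, 0,
               (m - (n - 1)) / (n * (n - 1) / 2 - (n - 1)))
  M <- length(partition$items)
  term <- ifelse(n <= 2L, 0, m * (m - (n - 1)) / ((n - 2) * (n - 1)))
  list(D = 2 / M * sum(term),
       per_cluster = data.frame(cluster = names(cl), m = m, n = n, D_C = dc,
                                row.names = NULL))
}

#' Trivial partition placing all items in one cluster
#' @param items Item names (edge keys or node names).
#' @return An `egdv_partition` with K = 1.
#' @export
single_cluster_partition <- function(items) {
  .make_partition(stats::setNames(rep(1L, length(items)), items))
}

#' Choose a partition from a dendrogram
#'
#' Scans the achievable cut levels of a dendrogram (one partition per
#' distinct merge level) and returns the partition optimising the chosen
#' objective:
#' \describe{
#'   \item{`max_density`}{maximum partition density D (edge partitions).}
#'   \item{`max_density_cc_capped`}{maximum D among partitions whose
#'     cluster coverage does not exceed `cc_cap`; this guards against the
#'     strong negative correlation between coverage and the per-cluster
#'     quality measures, which otherwise rewards low-coverage partitions.
#'     Falls back to `max_density` if no level satisfies the cap.}
#'   \item{`best_overall_quality`}{maximum overall partition quality (sum
#'     of the four coverage/quality measures, normalised across the
#'     scanned levels); requires `annotations`.}
#' }
#'
#' @param dendrogram An `egdv_dendrogram`.
#' @param strategy One of `"max_density"`, `"max_density_cc_capped"`,
#'   `"best_overall_quality"`.
#' @param node_universe Node universe for coverage measures (defaults to
#'   all nodes appearing in the clustered items).
#' @param cc_cap Cluster-coverage cap, required for
#'   `"max_density_cc_capped"`.
#' @param annotations Annotation list (see [cluster_quality()]), required
#'   for `"best_overall_quality"`.
#' @param levels Optional integer vector of K values to scan (default: all
#'   achievable levels).
#' @return The selected `egdv_partition`, with the scanned objective values
#'   attached as attribute `"scan"`.
#' @export
select_partition <- function(dendrogram,
                             strategy = c("max_density",
                                          "max_density_cc_capped",
                                          "best_overall_quality"),
                             node_universe = NULL,
                             cc_cap = NULL,
                             annotations = NULL,
                             levels = NULL) {
  strategy <- match.arg(strategy)
  if (strategy == "max_density_cc_capped" && is.null(cc_cap))
    stop("cc_cap is required for strategy 'max_density_cc_capped'")
  if (strategy == "best_overall_quality" && is.null(annotations))
    stop("annotations are required for strategy 'best_overall_quality'")
  n <- length(dendrogram$items)
  if (is.null(levels)) {
    h <- if (n >= 2) dendrogram$hclust$height else numeric(0)
    # achievable merge counts: end of each tie block, plus none/all
    ends <- which(diff(c(h, Inf)) != 0)
    levels <- unique(c(n, n - ends))
    levels <- levels[levels >= 1]
  }
  parts <- lapply(sort(levels, decreasing = TRUE),
                  function(K) cut_dendrogram(dendrogram, K))
  # deduplicate (tie blocks can collapse several requested K to one)
  achieved <- vapply(parts, `[[`, 0L, "K")
  parts <- parts[!duplicated(achieved)]
  achieved <- achieved[!duplicated(achieved)]

  if (strategy %in% c("max_density", "max_density_cc_capped")) {
    D <- vapply(parts, function(p) partition_density(p)$D, 0)
    scan <- data.frame(K = achieved, D = D)
    pick <- seq_along(parts)
    if (strategy == "max_density_cc_capped") {
      if (is.null(node_universe))
        node_universe <- .default_universe(parts[[1L]])
      cc <- vapply(parts, cluster_coverage, 0,
                   node_universe = node_universe)
      scan$CC <- cc
      ok <- which(cc <= cc_cap + 1e-12)
      if (length(ok)) pick <- ok
    }
    best <- pick[which.max(D[pick])]
  } else {
    if (is.null(node_universe))
      node_universe <- .default_universe(parts[[1L]])
    reports <- lapply(parts, quality_report,
                      node_universe = node_universe,
                      annotations = annotations)
    scored <- normalize_and_score(reports)
    overall <- vapply(scored, `[[`, 0, "overall")
    scan <- data.frame(K = achieved, overall = overall)
    best <- which.max(overall)
  }
  out <- parts[[best]]
  attr(out, "scan") <- scan
  out
}

.default_universe <- function(partition) {
  if (partition$kind == "edge")
    unique(as.vector(.edge_endpoints(partition$items)))
  else partition$items
}

#' k-medoids clustering on a precomputed distance
#'
#' A k-means variant whose centres are actual items.  Starting from a
#' uniform random sample of K distinct medoids (under the required seed),
#' it alternates (i) assigning every item to its nearest medoid and
#' (ii) replacing each cluster's medoid by the item minimising the total
#' intra-cluster distance, until the medoid set stabilises or `max_iter`
#' alternations have run.  Both steps are non-increasing in the total cost,
#' and ties are broken towards the smallest item index, so a run is fully
#' reproducible given the seed.  With GDV similarities the natural distance
#' is `1 - S`.
#'
#' @param distance Symmetric distance matrix with item names.
#' @param K Number of clusters (medoids), at most the number of items.
#' @param seed Integer seed for the random initialisation (required).
#' @param max_iter Iteration cap; if reached without stabilisation the
#'   best-so-far partition is returned with `converged = FALSE`.
#' @return An `egdv_partition` with extra fields `medoids` (item names),
#'   `cost` (final total distance), `cost_trace`, `converged`.
#' @export
k_medoids <- function(distance, K, seed, max_iter = 300L) {
  items <- rownames(distance)
  n <- length(items)
  if (K > n) stop("K exceeds the number of items")
  medoids <- sort(.with_seed(seed, sample.int(n, K)))
  cost_trace <- numeric(0)
  assign_items <- function(med) {
    sub <- distance[, med, drop = FALSE]
    cl <- max.col(-sub, ties.method = "first")
    list(cluster = cl, cost = sum(sub[cbind(seq_len(n), cl)]))
  }
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    a <- assign_items(medoids)
    cost_trace <- c(cost_trace, a$cost)
    new_med <- medoids
    for (c in seq_len(K)) {
      members <- which(a$cluster == c)
      if (!length(members)) next
      tot <- colSums(distance[members, members, drop = FALSE])
      new_med[c] <- members[which.min(tot)]
    }
    new_med <- sort(new_med)
    if (identical(new_med, medoids)) { converged <- TRUE; break }
    medoids <- new_med
  }
  a <- assign_items(medoids)
  cost_trace <- c(cost_trace, a$cost)
  if (!converged)
    message("k-medoids did not stabilise within ", max_iter, " iterations")
  p <- .make_partition(stats::setNames(a$cluster, items))
  p$medoids <- items[medoids]
  p$cost <- a$cost
  p$cost_trace <- cost_trace
  p$converged <- converged
  p
}
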