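# GDV similarities and the shared-neighbourhood (edge-SN) measure.

#' Per-orbit GDV distance component
#'
#' The weighted, log-scaled distance between the counts of one orbit in two
#' graphlet degree vectors:
#' \deqn{D_i(e,f) = w_i \, \frac{|\log(e_i+1) - \log(f_i+1)|}{\log(\max(e_i,f_i)+2)}.}
#' The logarithms damp order-of-magnitude differences, the denominator makes
#' the component relative (and bounds it strictly below \eqn{w_i}), and the
#' +1/+2 constants keep everything finite.  Vectorised over orbits.
#'
#' @param e_i,f_i Non-negative orbit counts (recycled as usual).
#' @param w_i Orbit weights in (0, 1].
#' @return Numeric vector of distance components in `[0, w_i)`.
#' @examples
#' gdv_distance_component(0, 1, 1)   # log(2)/log(3)
#' @export
gdv_distance_component <- function(e_i, f_i, w_i) {
  if (any(e_i < 0) || any(f_i < 0)) stop("orbit counts must be non-negative")
  w_i * abs(log(e_i + 1) - log(f_i + 1)) / log(pmax(e_i, f_i) + 2)
}

# Shared similarity kernel for a pair of count vectors.
.gdv_similarity <- function(a, b, w) {
  1 - sum(gdv_distance_component(a, b, w)) / sum(w)
}

#' Edge-GDV-similarity between two edges
#'
#' Compares two 68-element edge graphlet degree vectors:
#' \eqn{D(e,f) = \sum_i D_i(e,f) / \sum_i w_i} and
#' \eqn{S(e,f) = 1 - D(e,f)}.  S lies in (0, 1], equals 1 exactly for
#' identical vectors, and is symmetric.  Unlike the shared-neighbourhood
#' measure it is defined for any pair of edges, adjacent or not, and
#' compares their extended (up to 4-deep) topological neighbourhoods.
#'
#' @param gdv_e,gdv_f Length-68 edge-GDV count vectors
#'   (rows of [count_edge_gdv()]).
#' @param weights Edge-orbit weights from [edge_orbit_weights()].
#' @return Similarity in (0, 1].
#' @export
edge_gdv_similarity <- function(gdv_e, gdv_f, weights = edge_orbit_weights()) {
  if (length(gdv_e) != 68L || length(gdv_f) != 68L)
    stop("edge-GDVs must have 68 elements")
  .gdv_similarity(gdv_e, gdv_f, weights$w)
}

#' Node-GDV-similarity between two nodes
#'
#' The node analogue of [edge_gdv_similarity()], over the 73 node orbits
#' with node-orbit dependency weights (normaliser \eqn{\log 73}).
#'
#' @param gdv_u,gdv_v Length-73 node-GDV count vectors
#'   (rows of [count_node_gdv()]).
#' @param weights Node-orbit weights from [node_orbit_weights()].
#' @return Similarity in (0, 1].
#' @export
node_gdv_similarity <- function(gdv_u, gdv_v, weights = node_orbit_weights()) {
  if (length(gdv_u) != 73L || length(gdv_v) != 73L)
    stop("node-GDVs must have 73 elements")
  .gdv_similarity(gdv_u, gdv_v, weights$w)
}

# Dense pairwise similarity for a GDV count matrix.
.gdv_similarity_matrix <- function(counts, w) {
  n <- nrow(counts)
  S <- matrix(1, n, n, dimnames = list(rownames(counts), rownames(counts)))
  if (n < 2L) return(S)
  L <- log(counts + 1)
  sw <- sum(w)
  for (i in seq_len(n - 1L)) {
    rest <- (i + 1L):n
    Li <- matrix(L[i, ], length(rest), ncol(L), byrow = TRUE)
    Ci <- matrix(counts[i, ], length(rest), ncol(L), byrow = TRUE)
    num <- abs(L[rest, , drop = FALSE] - Li) /
      log(pmax(counts[rest, , drop = FALSE], Ci) + 2)
    d <- as.vector(num %*% w) / sw
    S[i, rest] <- S[rest, i] <- 1 - d
  }
  S
}

#' Pairwise edge-GDV-similarity matrix
#'
#' Computes [edge_gdv_similarity()] for all pairs of edges (the
#' unrestricted, "adjacent and non-adjacent" variant) or only for adjacent
#' edge pairs, in which case non-adjacent pairs are assigned similarity 0,
#' the infimum of the scale, so that hierarchical clustering never merges
#' through them before any adjacent pair.
#'
#' @param edge_gdv Edge-GDV count matrix from [count_edge_gdv()].
#' @param weights Edge-orbit weights, from [edge_orbit_weights()].
#' @param graph The graph (required when `adjacent_only = TRUE`, to know
#'   which edges share an endpoint).
#' @param adjacent_only Restrict to adjacent edge pairs?
#' @return Symmetric similarity matrix with unit diagonal, rows/columns
#'   named by edge key.
#' @export
edge_gdv_similarity_matrix <- function(edge_gdv,
                                       weights = edge_orbit_weights(),
                                       graph = NULL,
                                       adjacent_only = FALSE) {
  S <- .gdv_similarity_matrix(edge_gdv, weights$w)
  if (adjacent_only) {
    if (is.null(graph)) stop("adjacent_only = TRUE requires the graph")
    adj <- edge_adjacency(graph)[rownames(S), rownames(S)]
    S[!adj] <- 0
    diag(S) <- 1
  }
  S
}

#' Pairwise node-GDV-similarity matrix
#'
#' @param node_gdv Node-GDV count matrix from [count_node_gdv()].
#' @param weights Node-orbit weights, from [node_orbit_weights()].
#' @return Symmetric similarity matrix with unit diagonal.
#' @export
node_gdv_similarity_matrix <- function(node_gdv,
                                       weights = node_orbit_weights()) {
  .gdv_similarity_matrix(node_gdv, weights$w)
}

#' Which edge pairs are adjacent?
#'
#' @param graph Graph-like input.
#' @return Logical matrix over edge keys; `TRUE` where two distinct edges
#'   share exactly one endpoint (diagonal is `TRUE`).
#' @export
edge_adjacency <- function(graph) {
  g <- as_ppi_graph(graph)
  keys <- edge_keys(g)
  ends <- .edge_endpoints(keys)
  m <- length(keys)
  adj <- diag(m) > 0
  dimnames(adj) <- list(keys, keys)
  inc <- lapply(igraph::V(g)$name, function(v)
    which(ends[, 1] == v | ends[, 2] == v))
  for (ii in inc) {
    if (length(ii) > 1L) adj[ii, ii] <- TRUE
  }
  adj
}

#' Shared-neighbourhood (edge-SN) similarity of two adjacent edges
#'
#' For edges \eqn{e_{ik}} and \eqn{e_{jk}} sharing exactly the node
#' \eqn{k}, the Jaccard coefficient of the inclusive neighbourhoods of the
#' non-shared endpoints:
#' \deqn{S(e_{ik}, e_{jk}) = |n(i) \cap n(j)| / |n(i) \cup n(j)|,}
#' where \eqn{n(i)} is node \eqn{i} together with its neighbours.  This is
#' the similarity underlying shared-neighbourhood link clustering; it
#' effectively counts the 3-node paths the end nodes share and is only
#' defined for adjacent edges.
#'
#' @param graph Graph-like input.
#' @param edge_a,edge_b Edges, each as a length-2 character vector of
#'   endpoint names or an `"a|b"` edge key.
#' @return Similarity in `[0, 1]`.
#' @examples
#' p3 <- igraph::make_graph(~ i - k, k - j)
#' edge_sn_similarity(p3, c("i", "k"), c("k", "j"))   # 1/3
#' @export
edge_sn_similarity <- function(graph, edge_a, edge_b) {
  g <- as_ppi_graph(graph)
  norm <- function(e) {
    if (length(e) == 1L) e <- strsplit(e, "|", fixed = TRUE)[[1]]
    as.character(e)
  }
  ea <- norm(edge_a); eb <- norm(edge_b)
  shared <- intersect(ea, eb)
  if (setequal(ea, eb)) stop("edges are identical")
  if (length(shared) != 1L) stop("edges must share exactly one endpoint")
  i <- setdiff(ea, shared); j <- setdiff(eb, shared)
  ni <- c(i, igraph::neighbors(g, i)$name)
  nj <- c(j, igraph::neighbors(g, j)$name)
  length(intersect(ni, nj)) / length(union(ni, nj))
}

#' Pairwise edge-SN similarity matrix
#'
#' [edge_sn_similarity()] for every adjacent edge pair; non-adjacent pairs
#' get 0 and the diagonal is 1.
#'
#' @param graph Graph-like input.
#' @return Symmetric similarity matrix over edge keys.
#' @export
edge_sn_similarity_matrix <- function(graph) {
  g <- as_ppi_graph(graph)
  keys <- edge_keys(g)
  ends <- .edge_endpoints(keys)
  m <- length(keys)
  S <- diag(m)
  dimnames(S) <- list(keys, keys)
  vn <- igraph::V(g)$name
  nbr <- lapply(vn, function(v) c(v, igraph::neighbors(g, v)$name))
  names(nbr) <- vn
  inc <- lapply(vn, function(v) which(ends[, 1] == v | ends[, 2] == v))
  names(inc) <- vn
  for (k in vn) {
    ii <- inc[[k]]
    if (length(ii) < 2L) next
    for (a in seq_len(length(ii) - 1L)) for (b in (a + 1L):length(ii)) {
      e1 <- ii[a]; e2 <- ii[b]
      i <- setdiff(ends[e1, ], k); j <- setdiff(ends[e2, ], k)
      if (identical(i, j)) next   # parallel via both endpoints impossible in simple graph
      s <- length(intersect(nbr[[i]], nbr[[j]])) /
        length(union(nbr[[i]], nbr[[j]]))
      # two edges can share either endpoint; keep the larger similarity if
      # both shared nodes connect them (triangle case computes the same s)
      S[e1, e2] <- S[e2, e1] <- max(S[e1, e2], s)
    }
  }
  S
}
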