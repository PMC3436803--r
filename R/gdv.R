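# Exact graphlet degree vector counting.
#
# Strategy: enumerate every connected induced subgraph on 2-5 nodes exactly
# once (Wernicke's ESU extension scheme), then classify each subgraph and
# read off the orbit of every node position and edge position from the
# atlas lookup tables, which map a labelled adjacency code directly to
# global orbit ids.  Each enumerated subgraph therefore increments exactly
# one orbit count of each of its nodes and each of its edges.

# Enumerate connected induced subgraphs of sizes 2..kmax, each exactly once.
# adj: list of sorted integer neighbour vectors.  Returns a list indexed by
# size k of matrices with k columns (node ids, ascending within each row).
.esu <- function(adj, n, kmax = 5L) {
  store <- vector("list", kmax)
  used <- integer(kmax)
  for (k in 2:kmax) store[[k]] <- matrix(0L, 64L, k)
  record <- function(sub) {
    k <- length(sub)
    if (used[k] == nrow(store[[k]]))
      store[[k]] <<- rbind(store[[k]], matrix(0L, nrow(store[[k]]), k))
    used[k] <<- used[k] + 1L
    store[[k]][used[k], ] <<- sort.int(sub)
  }
  extend <- function(sub, ext, v, visited) {
    if (length(sub) >= 2L) record(sub)
    if (length(sub) == kmax) return(invisible())
    while (length(ext)) {
      w <- ext[1L]
      ext <- ext[-1L]
      nb <- adj[[w]]
      excl <- nb[nb > v & !visited[nb]]
      vis2 <- visited
      vis2[excl] <- TRUE
      extend(c(sub, w), c(ext, excl), v, vis2)
    }
  }
  for (v in seq_len(n)) {
    nb <- adj[[v]]
    ext <- nb[nb > v]
    visited <- logical(n)
    visited[v] <- TRUE
    visited[nb] <- TRUE
    extend(v, ext, v, visited)
  }
  for (k in 2:kmax)
    store[[k]] <- store[[k]][seq_len(used[k]), , drop = FALSE]
  store
}

# Shared counting core.  Returns list(node = n x 73, edge = m x 68).
.count_gdv <- function(graph, atlas = graphlet_atlas()) {
  g <- as_ppi_graph(graph)
  n <- igraph::vcount(g)
  vnames <- igraph::V(g)$name
  n_norb <- atlas$n_node_orbits
  n_eorb <- atlas$n_edge_orbits - 1L   # edge orbit 0 is excluded
  em <- igraph::as_edgelist(g, names = FALSE)
  m <- nrow(em)
  node_acc <- numeric(n * n_norb)
  edge_acc <- numeric(max(m, 1L) * n_eorb)
  if (n > 0L && m > 0L) {
    A <- matrix(FALSE, n, n)
    A[em] <- TRUE
    A[em[, 2:1, drop = FALSE]] <- TRUE
    adj <- lapply(seq_len(n), function(v) which(A[v, ]))
    eid <- seq_len(m)
    names(eid) <- paste(pmin(em[, 1], em[, 2]), pmax(em[, 1], em[, 2]))
    subs <- .esu(adj, n, 5L)
    for (k in 2:5) {
      S <- subs[[k]]
      if (is.null(S) || nrow(S) == 0L) next
      prs <- atlas$pairs[[k]]
      np <- ncol(prs)
      bits <- matrix(0L, nrow(S), np)
      for (t in seq_len(np))
        bits[, t] <- A[cbind(S[, prs[1L, t]], S[, prs[2L, t]])]
      code <- as.vector(bits %*% 2^(seq_len(np) - 1)) + 1L
      for (pos in seq_len(k)) {
        orb <- atlas$node_lut[[k]][cbind(code, pos)]
        idx <- (S[, pos] - 1L) * n_norb + orb + 1L
        node_acc <- node_acc + tabulate(idx, length(node_acc))
      }
      if (k >= 3L) {
        for (t in seq_len(np)) {
          present <- bits[, t] == 1L
          if (!any(present)) next
          orb <- atlas$edge_lut[[k]][cbind(code[present], t)]
          a <- S[present, prs[1L, t]]
          b <- S[present, prs[2L, t]]
          ids <- eid[paste(pmin(a, b), pmax(a, b))]
          idx <- (ids - 1L) * n_eorb + orb
          edge_acc <- edge_acc + tabulate(idx, length(edge_acc))
        }
      }
    }
  }
  node <- matrix(as.integer(node_acc), n, n_norb, byrow = TRUE)
  rownames(node) <- vnames
  colnames(node) <- paste0("o", seq_len(n_norb) - 1L)
  edge <- matrix(as.integer(edge_acc), max(m, 1L), n_eorb, byrow = TRUE)
  if (m == 0L) edge <- edge[0L, , drop = FALSE]
  rownames(edge) <- if (m > 0L)
    paste(pmin(vnames[em[, 1]], vnames[em[, 2]]),
          pmax(vnames[em[, 1]], vnames[em[, 2]]), sep = "|") else character(0)
  colnames(edge) <- paste0("o", seq_len(n_eorb))
  list(node = node, edge = edge)
}

#' Node graphlet degree vectors
#'
#' For every node of an undirected simple graph, counts the number of
#' connected induced subgraphs on 2-5 nodes (graphlets) that touch the node
#' at each of the 73 automorphism node orbits.  Element `o0` is the node's
#' degree.  The vector summarises the topology of the node's up-to-4-deep
#' neighbourhood.
#'
#' @param graph An `igraph` object, a two-column edge data frame, or a path
#'   readable by [read_edge_list()].
#' @param atlas A graphlet atlas, from [graphlet_atlas()].
#' @return Integer matrix, one row per node (named), 73 orbit columns
#'   `o0..o72`.
#' @examples
#' tri <- igraph::make_ring(3)
#' igraph::V(tri)$name <- c("a", "b", "c")
#' count_node_gdv(tri)["a", 1:5]
#' @export
count_node_gdv <- function(graph, atlas = graphlet_atlas()) {
  .count_gdv(graph, atlas)$node
}

#' Edge graphlet degree vectors
#'
#' For every edge, counts the number of connected induced subgraphs on 3-5
#' nodes that touch the edge at each of the 68 automorphism edge orbits
#' (orbits 1-68; orbit 0, the edge itself as the 2-node graphlet, is
#' excluded since every edge touches exactly one).  Each qualifying node
#' subset increments exactly one orbit of each edge it contains.
#'
#' @inheritParams count_node_gdv
#' @return Integer matrix, one row per edge (named `"a|b"` with endpoint
#'   names in sorted order), 68 orbit columns `o1..o68`.
#' @examples
#' p4 <- igraph::make_graph(~ a - b, b - c, c - d)
#' count_edge_gdv(p4)["b|c", c("o1", "o4")]   # 2 three-paths, 1 mid-of-4-path
#' @export
count_edge_gdv <- function(graph, atlas = graphlet_atlas()) {
  .count_gdv(graph, atlas)$edge
}
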