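# Independent brute-force GDV oracle.
#
# Counts node and edge orbits by iterating over ALL node subsets of size
# 2..5 (utils::combn), testing induced connectivity with a plain BFS, and
# classifying each connected induced subgraph by exhaustive isomorphism
# search (igraph's VF2) against the atlas representatives.  It shares only
# the atlas's orbit numbering with the production counter, not its
# enumeration or classification machinery.

oracle_gdv <- function(graph, atlas = graphlet_atlas()) {
  g <- as_ppi_graph(graph)
  n <- igraph::vcount(g)
  A <- as.matrix(igraph::as_adjacency_matrix(g)) > 0
  vnames <- igraph::V(g)$name
  # atlas representatives as igraph objects, grouped by (n, m)
  reps <- lapply(atlas$reps, function(r)
    igraph::graph_from_edgelist(t(r$edges), directed = FALSE))
  rep_n <- vapply(atlas$reps, `[[`, 0L, "n")
  rep_m <- vapply(atlas$reps, `[[`, 0L, "m")

  node_counts <- matrix(0L, n, atlas$n_node_orbits,
                        dimnames = list(vnames,
                                        paste0("o", seq_len(atlas$n_node_orbits) - 1L)))
  ekeys <- edge_keys(g)
  edge_counts <- matrix(0L, length(ekeys), atlas$n_edge_orbits - 1L,
                        dimnames = list(ekeys,
                                        paste0("o", seq_len(atlas$n_edge_orbits - 1L))))
  connected <- function(S) {
    k <- length(S)
    seen <- logical(k); seen[1] <- TRUE; frontier <- 1L
    Asub <- A[S, S, drop = FALSE]
    while (length(frontier)) {
      nxt <- which(colSums(Asub[frontier, , drop = FALSE]) > 0 & !seen)
      seen[nxt] <- TRUE; frontier <- nxt
    }
    all(seen)
  }
  for (k in 2:min(5L, n)) {
    subsets <- utils::combn(n, k)
    for (ci in seq_len(ncol(subsets))) {
      S <- subsets[, ci]
      if (!connected(S)) next
      Asub <- A[S, S, drop = FALSE]
      sub <- igraph::graph_from_adjacency_matrix(Asub, mode = "undirected")
      m <- sum(Asub) / 2
      gid <- which(rep_n == k & rep_m == m)
      hit <- NULL
      for (gi in gid) {
        iso <- igraph::isomorphisms(sub, reps[[gi]])
        if (length(iso)) {
          hit <- gi
          # igraph returns the map indexed by the second graph's vertices
          # (m[rep] = sub); invert to get phi: sub -> rep
          m <- as.integer(iso[[1]])
          phi <- integer(length(m)); phi[m] <- seq_along(m)
          break
        }
      }
      stopifnot(!is.null(hit))
      norb <- atlas$node_orbits[[hit]]
      for (i in seq_len(k)) {
        o <- norb[phi[i]]
        node_counts[S[i], o + 1L] <- node_counts[S[i], o + 1L] + 1L
      }
      if (k >= 3) {
        pidx <- egdv:::.pair_index_matrix(k)
        eorb <- atlas$edge_orbits[[hit]]
        for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
          if (!Asub[i, j]) next
          rep_pidx <- egdv:::.pair_index_matrix(atlas$reps[[hit]]$n)
          o <- eorb[rep_pidx[phi[i], phi[j]]]
          key <- paste(min(vnames[S[i]], vnames[S[j]]),
                       max(vnames[S[i]], vnames[S[j]]), sep = "|")
          edge_counts[key, o] <- edge_counts[key, o] + 1L
        }
      }
    }
  }
  list(node = node_counts, edge = edge_counts)
}
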