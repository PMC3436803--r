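# Small named graphs used across the test files.

toy_graph <- function(which) {
  g <- switch(which,
    edge = igraph::make_graph(~ a - b),
    path3 = igraph::make_graph(~ a - b, b - c),
    path4 = igraph::make_graph(~ a - b, b - c, c - d),
    triangle = igraph::make_graph(~ a - b, b - c, c - a),
    star5 = igraph::make_star(5, mode = "undirected"),
    clique5 = igraph::make_full_graph(5),
    stop("unknown toy"))
  if (is.null(igraph::V(g)$name))
    igraph::V(g)$name <- letters[seq_len(igraph::vcount(g))]
  g
}

random_named_gnp <- function(n, p, seed) {
  g <- egdv:::.with_seed(seed, {
    prs <- utils::combn(n, 2L)
    keep <- stats::runif(ncol(prs)) < p
    gg <- igraph::graph_from_edgelist(t(prs[, keep, drop = FALSE]),
                                      directed = FALSE)
    igraph::add_vertices(gg, max(0L, n - igraph::vcount(gg)))
  })
  igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
  g
}

# Standard planted test bed: spec'd block structure with pathogen modules.
planted_fixture <- function(seed = 1L) {
  g <- make_graph_fixture("planted_partition", blocks = 4L, block_size = 8L,
                          p_within = 0.8, p_between = 0.02, seed = seed)
  list(
    graph = g,
    annotations = make_annotations(g, purity = 0.9, seed = seed + 100L),
    pathogen_map = make_pathogen_map(g, n_pathogens = 4L,
                                     within_fraction = 0.9,
                                     n_interactors = 6L, seed = seed + 200L))
}
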