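# Seed-deterministic synthetic inputs: toy graphs, uniform random graphs,
# planted-partition graphs, planted annotation structure and planted
# pathogen-interaction modules.  These emulate the statistical structure
# the clustering-and-enrichment workflow exploits — topologically coherent
# edge groups with concentrated annotations and pathogen interactors — not
# the degree distribution or assay biases of real interactome data.

#' Generate a synthetic graph
#'
#' Supported generators:
#' \describe{
#'   \item{named toys}{`"edge"`, `"path"` (with `n`), `"triangle"`,
#'     `"cycle"` (`n`), `"clique"` (`n`), `"star"` (`n` = total nodes).}
#'   \item{`"gnp"`}{uniform random graph, each of the `choose(n, 2)` edges
#'     present independently with probability `p`.}
#'   \item{`"planted_partition"`}{`blocks` blocks of `block_size` nodes;
#'     within-block edge probability `p_within`, between-block
#'     `p_between`.  Vertex attribute `block` carries the planted truth.}
#' }
#' Nodes are named `p001, p002, ...`; generation is fully determined by
#' the arguments and `seed`.
#'
#' @param generator Generator name (see above).
#' @param n Number of nodes (toys and `gnp`).
#' @param p Edge probability for `gnp`.
#' @param blocks,block_size,p_within,p_between Planted-partition shape.
#' @param seed Integer seed (required for the random generators).
#' @return An undirected simple `igraph`; planted-partition graphs carry a
#'   `block` vertex attribute.
#' @examples
#' g <- make_graph_fixture("planted_partition", blocks = 2, block_size = 5,
#'                         p_within = 1, p_between = 0, seed = 1)
#' table(igraph::V(g)$block)
#' @export
make_graph_fixture <- function(generator,
                               n = NULL, p = NULL,
                               blocks = 4L, block_size = 8L,
                               p_within = 0.8, p_between = 0.02,
                               seed = NULL) {
  name_nodes <- function(g) {
    igraph::V(g)$name <- sprintf("p%03d", seq_len(igraph::vcount(g)))
    g
  }
  bernoulli_graph <- function(n, prob_fun) {
    prs <- utils::combn(n, 2L)
    probs <- prob_fun(prs[1L, ], prs[2L, ])
    keep <- stats::runif(ncol(prs)) < probs
    g <- igraph::graph_from_edgelist(t(prs[, keep, drop = FALSE]),
                                     directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
    g
  }
  g <- switch(generator,
    edge = igraph::make_graph(c(1, 2), directed = FALSE),
    triangle = igraph::make_ring(3),
    path = igraph::make_graph(rep(seq_len(n %||% 4L), each = 2)[
      -c(1, 2 * (n %||% 4L))], directed = FALSE),
    cycle = igraph::make_ring(n %||% 5L),
    clique = igraph::make_full_graph(n %||% 5L),
    star = igraph::make_star(n %||% 5L, mode = "undirected"),
    gnp = {
      if (is.null(seed)) stop("gnp requires a seed")
      .with_seed(seed, bernoulli_graph(n %||% 20L, function(i, j) p %||% 0.2))
    },
    planted_partition = {
      if (is.null(seed)) stop("planted_partition requires a seed")
      ntot <- blocks * block_size
      memb <- rep(seq_len(blocks), each = block_size)
      gg <- .with_seed(seed, bernoulli_graph(ntot, function(i, j)
        ifelse(memb[i] == memb[j], p_within, p_between)))
      igraph::V(gg)$block <- memb
      gg
    },
    stop("unknown generator: ", generator))
  name_nodes(igraph::simplify(g))
}

# Planted block membership of a graph's nodes, as a named integer vector.
.blocks_of <- function(graph) {
  b <- igraph::V(graph)$block
  if (is.null(b)) stop("graph has no planted 'block' attribute")
  stats::setNames(as.integer(b), igraph::V(graph)$name)
}

#' Planted annotations for a blocked graph
#'
#' Assigns each block a dominant term (`T1, T2, ...`).  Every node
#' receives its block's dominant term with probability `purity` and a
#' uniformly random other term otherwise; with rate `extra_rate` a node
#' additionally gets a second random term, so per-node term counts vary
#' (needed for a non-degenerate overlap-quality signal).
#'
#' @param graph A graph with a planted `block` vertex attribute, or a
#'   named block vector.
#' @param purity Probability that a node carries its own block's term.
#' @param extra_rate Probability of one extra random term per node.
#' @param seed Integer seed (required).
#' @return Named list node -> character vector of terms.
#' @export
make_annotations <- function(graph, purity = 0.9, extra_rate = 0.2,
                             seed = NULL) {
  if (is.null(seed)) stop("make_annotations requires a seed")
  stopifnot(purity >= 0, purity <= 1)
  blocks <- if (igraph::is_igraph(graph)) .blocks_of(graph) else graph
  terms <- paste0("T", sort(unique(blocks)))
  .with_seed(seed, {
    ann <- lapply(names(blocks), function(v) {
      own <- paste0("T", blocks[[v]])
      t1 <- if (stats::runif(1) < purity || length(terms) == 1L) own
            else sample(setdiff(terms, own), 1L)
      t2 <- if (stats::runif(1) < extra_rate) sample(terms, 1L) else NULL
      unique(c(t1, t2))
    })
    stats::setNames(ann, names(blocks))
  })
}

#' Planted pathogen-interaction map for a blocked graph
#'
#' Each pathogen (`X1, X2, ...`) is assigned a home block and draws
#' `n_interactors` host proteins, a fraction `within_fraction` of them
#' from its home block and the rest from the other blocks.  Interactors
#' are sampled preferentially among nodes with degree above `min_degree`,
#' and at least two such interactors are guaranteed where possible, so
#' that the pathogen survives [eligible_universe()].
#'
#' @param graph A graph with a planted `block` vertex attribute.
#' @param n_pathogens Number of pathogens.
#' @param within_fraction Fraction of each pathogen's interactors drawn
#'   from its home block.
#' @param n_interactors Interactors per pathogen (default 4).
#' @param min_degree Degree rule used downstream (default 3).
#' @param seed Integer seed (required).
#' @return Data frame with columns `protein`, `pathogen`.
#' @export
make_pathogen_map <- function(graph, n_pathogens = 4L,
                              within_fraction = 0.9,
                              n_interactors = 4L, min_degree = 3L,
                              seed = NULL) {
  if (is.null(seed)) stop("make_pathogen_map requires a seed")
  stopifnot(within_fraction >= 0, within_fraction <= 1)
  blocks <- .blocks_of(graph)
  deg <- igraph::degree(graph)
  eligible <- names(deg)[deg > min_degree]
  pick <- function(pool, k) {
    # prefer high-degree nodes so associations survive the degree filter
    pool_hi <- intersect(pool, eligible)
    chosen <- if (length(pool_hi)) sample(pool_hi, min(k, length(pool_hi)))
              else character(0)
    extra <- setdiff(pool, chosen)
    if (length(chosen) < k && length(extra))
      chosen <- c(chosen, sample(extra, min(k - length(chosen), length(extra))))
    chosen
  }
  .with_seed(seed, {
    rows <- lapply(seq_len(n_pathogens), function(i) {
      home <- ((i - 1L) %% max(blocks)) + 1L
      n_in <- round(within_fraction * n_interactors)
      own <- pick(names(blocks)[blocks == home], n_in)
      oth <- pick(names(blocks)[blocks != home], n_interactors - length(own))
      data.frame(protein = c(own, oth), pathogen = paste0("X", i))
    })
    unique(do.call(rbind, rows))
  })
}

#' Write a fixture to disk as plain TSV files
#'
#' Writes `edges.tsv` (two columns), `annotations.tsv` (node, term),
#' `pathogens.tsv` (protein, pathogen) and `truth.tsv` (node, planted
#' block) into `dir`.  Regenerating with the same arguments and seed
#' yields byte-identical files.
#'
#' @param dir Output directory (created if needed).
#' @param graph Graph from [make_graph_fixture()].
#' @param annotations Optional annotation list.
#' @param pathogen_map Optional association data frame.
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(dir, graph, annotations = NULL,
                          pathogen_map = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  el <- igraph::as_edgelist(graph)
  utils::write.table(el, file.path(dir, "edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  if (!is.null(annotations)) {
    df <- data.frame(node = rep(names(annotations), lengths(annotations)),
                     term = unlist(annotations))
    utils::write.table(df, file.path(dir, "annotations.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(pathogen_map))
    utils::write.table(pathogen_map, file.path(dir, "pathogens.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  if (!is.null(igraph::V(graph)$block))
    utils::write.table(
      data.frame(node = igraph::V(graph)$name,
                 block = igraph::V(graph)$block),
      file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
  invisible(dir)
}
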