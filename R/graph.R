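# Graph input and basic manipulation.  Networks are held as undirected
# simple igraph objects with character vertex names; edges are identified
# throughout by the key "a|b" with endpoint names in sorted order.

#' Coerce to an undirected simple named graph
#'
#' Accepts an `igraph` object, a two-column data frame / matrix of endpoint
#' labels, or a file path (delegated to [read_edge_list()]).  Self-loops and
#' duplicate edges are dropped; vertex names are required (labels are taken
#' as character).
#'
#' @param x Graph-like input.
#' @return An undirected simple `igraph` with a `name` vertex attribute.
#' @export
as_ppi_graph <- function(x) {
  if (igraph::is_igraph(x)) {
    g <- x
    if (igraph::is_directed(g)) g <- igraph::as_undirected(g, mode = "collapse")
    if (is.null(igraph::V(g)$name))
      igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
    return(igraph::simplify(g))
  }
  if (is.character(x) && length(x) == 1L) return(read_edge_list(x))
  if (is.matrix(x) || is.data.frame(x)) {
    el <- cbind(as.character(x[[1]]), as.character(x[[2]]))
    g <- igraph::graph_from_edgelist(el, directed = FALSE)
    return(igraph::simplify(g))
  }
  stop("cannot interpret input as a graph")
}

#' Read an undirected edge list from a TSV file
#'
#' Expects at least two tab- or whitespace-separated columns of node labels;
#' lines starting with `#` are ignored.  Self-loops and duplicate edges
#' (including reversed duplicates) are dropped; a single warning reports how
#' many of each were removed.
#'
#' @param path Path to the edge-list file.
#' @return An undirected simple `igraph`.  Attributes
#'   `n_self_loops_dropped` and `n_duplicates_dropped` record the sanitation
#'   counts.
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop("cannot read edge list: ", path)
  tab <- tryCatch(
    utils::read.table(path, header = FALSE, comment.char = "#",
                      colClasses = "character", fill = FALSE,
                      blank.lines.skip = TRUE),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e)))
        data.frame(V1 = character(0), V2 = character(0))
      else stop(e)
    })
  if (nrow(tab) > 0L && ncol(tab) < 2L)
    stop("edge list must have at least two columns: ", path)
  if (nrow(tab) == 0L) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    igraph::V(g)$name <- character(0)
    attr(g, "n_self_loops_dropped") <- 0L
    attr(g, "n_duplicates_dropped") <- 0L
    return(g)
  }
  a <- tab[[1]]; b <- tab[[2]]
  loops <- a == b
  key <- paste(pmin(a, b), pmax(a, b), sep = "\r")
  dups <- duplicated(key) & !loops
  keep <- !loops & !dups
  if (any(loops) || any(dups))
    warning(sprintf("dropped %d self-loop(s) and %d duplicate edge(s) from %s",
                    sum(loops), sum(dups), path))
  g <- igraph::graph_from_edgelist(cbind(a[keep], b[keep]), directed = FALSE)
  attr(g, "n_self_loops_dropped") <- sum(loops)
  attr(g, "n_duplicates_dropped") <- sum(dups)
  g
}

#' Canonical edge keys of a graph
#'
#' @param graph Graph-like input (see [as_ppi_graph()]).
#' @return Character vector `"a|b"` (endpoints sorted), in igraph edge
#'   order — the row order used by [count_edge_gdv()].
#' @export
edge_keys <- function(graph) {
  g <- as_ppi_graph(graph)
  el <- igraph::as_edgelist(g)
  paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), sep = "|")
}

.edge_endpoints <- function(keys) {
  parts <- strsplit(keys, "|", fixed = TRUE)
  cbind(vapply(parts, `[[`, "", 1L), vapply(parts, `[[`, "", 2L))
}

#' Filter out poorly connected nodes and their edges
#'
#' Keeps nodes with degree strictly greater than `min_degree` (degrees
#' measured on the unfiltered graph) and edges whose both endpoints pass.
#' Poorly connected proteins are disproportionately involved in noisy
#' interactions, so clustering and enrichment analyses are restricted to
#' the well-connected core while graphlet counts are still taken on the
#' full network.
#'
#' @param graph Graph-like input.
#' @param min_degree Keep nodes with degree > `min_degree` (default 3).
#' @return List with `nodes` (character), `edges` (edge keys `"a|b"`), and
#'   `graph` (the induced subgraph on the kept nodes).
#' @examples
#' star <- igraph::make_star(5, mode = "undirected")
#' igraph::V(star)$name <- letters[1:5]
#' degree_filter(star, 3)$nodes   # only the hub survives
#' @export
degree_filter <- function(graph, min_degree = 3L) {
  g <- as_ppi_graph(graph)
  stopifnot(min_degree >= 0L)
  deg <- igraph::degree(g)
  nodes <- igraph::V(g)$name[deg > min_degree]
  el <- igraph::as_edgelist(g)
  keep <- el[, 1] %in% nodes & el[, 2] %in% nodes
  edges <- paste(pmin(el[keep, 1], el[keep, 2]),
                 pmax(el[keep, 1], el[keep, 2]), sep = "|")
  list(nodes = nodes, edges = edges,
       graph = igraph::induced_subgraph(g, nodes))
}
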