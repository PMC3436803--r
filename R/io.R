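# Readers/writers for the tabular formats, the pipeline configuration and
# the end-to-end pipeline runner.

#' Read node annotations (node, term) from a TSV file
#'
#' @param path Two-column TSV (node, term), `#` comments ignored; multiple
#'   rows per node accumulate terms.
#' @return Named list node -> character vector of terms.
#' @export
read_annotations <- function(path) {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           colClasses = "character")
  lapply(split(tab[[2]], tab[[1]]), unique)
}

#' Read a protein-pathogen association table from a TSV file
#'
#' @param path Two-column TSV (protein, pathogen), `#` comments ignored.
#' @return Data frame with columns `protein`, `pathogen`, deduplicated.
#' @export
read_pathogen_map <- function(path) {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           colClasses = "character")
  .as_pathogen_map(tab)
}

#' Write a GDV matrix as TSV
#' @param gdv Matrix from [count_node_gdv()] or [count_edge_gdv()].
#' @param path Output path (item id column, then orbit count columns).
#' @export
write_gdv <- function(gdv, path) {
  utils::write.table(data.frame(item = rownames(gdv), gdv,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a GDV matrix written by [write_gdv()]
#' @param path TSV path.
#' @return Integer matrix with item row names.
#' @export
read_gdv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- tab[[1]]
  m
}

#' Write a similarity matrix in long format (item_a, item_b, similarity)
#' @param sim Symmetric similarity matrix.
#' @param path Output TSV path.
#' @param keep_zero Write zero-similarity pairs too? (default FALSE)
#' @export
write_similarity <- function(sim, path, keep_zero = FALSE) {
  idx <- which(upper.tri(sim), arr.ind = TRUE)
  df <- data.frame(item_a = rownames(sim)[idx[, 1]],
                   item_b = colnames(sim)[idx[, 2]],
                   similarity = sim[idx])
  if (!keep_zero) df <- df[df$similarity > 0, , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a partition as TSV (item, cluster)
#' @param partition An `egdv_partition`.
#' @param path Output TSV path.
#' @export
write_partition <- function(partition, path) {
  utils::write.table(data.frame(item = partition$items,
                                cluster = partition$assignment),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Pipeline configuration
#'
#' Bundles the workflow parameters with their conventional defaults: the
#' degree filter (> 3 interacting partners), K = 1250 clusters for
#' hierarchical clustering and K = 1000 for k-medoids (the values that
#' behave best on interactome-scale networks; smaller inputs should scale
#' K down), enrichment threshold k = 66%, significance cutoff 0.05, and
#' 100 randomisation runs for the baseline.
#'
#' @param min_degree Degree filter for clustering/enrichment (default 3).
#' @param K_hie Requested clusters for hierarchical strategies.
#' @param K_km Requested clusters for k-medoids strategies.
#' @param k Enrichment threshold in percent (default 66).
#' @param alpha Significance cutoff (default 0.05).
#' @param runs Randomisation runs for the baseline (default 100).
#' @param adjacent_only Restrict edge similarities to adjacent pairs?
#' @param seed Master seed for all stochastic steps.
#' @return A list of class `egdv_config`.
#' @export
egdv_config <- function(min_degree = 3L, K_hie = 1250L, K_km = 1000L,
                        k = 66, alpha = 0.05, runs = 100L,
                        adjacent_only = FALSE, seed = 1L) {
  structure(list(min_degree = min_degree, K_hie = K_hie, K_km = K_km,
                 k = k, alpha = alpha, runs = runs,
                 adjacent_only = adjacent_only, seed = seed),
            class = "egdv_config")
}

#' Run the clustering-and-prediction pipeline end to end
#'
#' Orchestrates one strategy: graphlet counting on the full network,
#' GDV-similarity, degree filtering, clustering (hierarchical with a
#' requested K or a density-based selection strategy, or k-medoids),
#' optional partition-quality evaluation, and — when associations are
#' supplied — enrichment, the LOOCV precision-recall sweep and new
#' predictions.  Reruns with the same config and inputs are reproducible.
#'
#' @param graph Graph-like input (path, data frame or igraph).
#' @param strategy One of `"edge-hie"`, `"node-hie"`, `"edge-km"`,
#'   `"node-km"`.
#' @param config An [egdv_config()].
#' @param annotations Optional annotation list or TSV path.
#' @param pathogen_map Optional association data frame or TSV path.
#' @param select Dendrogram selection: `"K"` (cut at the configured K) or
#'   a [select_partition()] strategy name.
#' @param out_dir Optional directory for artifact TSVs and the JSON
#'   summary.
#' @return List with `partition`, `quality`, `enrichment`, `pr_curve`,
#'   `predictions`, `summary` (the summary is also written to
#'   `out_dir/summary.json` when `out_dir` is given).
#' @export
run_pipeline <- function(graph, strategy = "edge-hie",
                         config = egdv_config(),
                         annotations = NULL, pathogen_map = NULL,
                         select = "K", out_dir = NULL) {
  strategy <- match.arg(strategy,
                        c("edge-hie", "node-hie", "edge-km", "node-km"))
  g <- as_ppi_graph(graph)
  if (is.character(annotations)) annotations <- read_annotations(annotations)
  atlas <- graphlet_atlas()
  mode <- if (startsWith(strategy, "edge")) "edge" else "node"
  method <- if (endsWith(strategy, "hie")) "hie" else "km"

  filt <- degree_filter(g, config$min_degree)
  if (mode == "edge") {
    gdv <- count_edge_gdv(g, atlas)[intersect(edge_keys(g), filt$edges), ,
                                    drop = FALSE]
    sim <- edge_gdv_similarity_matrix(gdv, edge_orbit_weights(atlas),
                                      graph = g,
                                      adjacent_only = config$adjacent_only)
  } else {
    gdv <- count_node_gdv(g, atlas)[filt$nodes, , drop = FALSE]
    sim <- node_gdv_similarity_matrix(gdv, node_orbit_weights(atlas))
  }
  n_items <- nrow(sim)
  if (method == "hie") {
    dend <- single_linkage(sim)
    if (identical(select, "K")) {
      K <- min(config$K_hie, n_items)
      partition <- cut_dendrogram(dend, K)
    } else {
      partition <- select_partition(dend, strategy = select,
                                    node_universe = filt$nodes,
                                    annotations = annotations)
    }
  } else {
    K <- min(config$K_km, n_items)
    partition <- k_medoids(1 - sim, K, seed = config$seed)
  }

  quality <- if (!is.null(annotations))
    quality_report(partition, annotations, node_universe = filt$nodes)
  enrichment <- pr_curve <- predictions <- baseline <- NULL
  if (!is.null(pathogen_map)) {
    elig <- eligible_universe(g, pathogen_map, config$min_degree)
    enrichment <- cluster_enrichment(partition, elig, config$alpha)
    pr_curve <- loocv_pr_curve(partition, elig, config$alpha)
    predictions <- predict_new(partition, elig, config$k, config$alpha,
                               method = strategy)
  }
  summary <- list(
    strategy = strategy,
    config = unclass(config),
    n_nodes = igraph::vcount(g), n_edges = igraph::ecount(g),
    n_filtered_nodes = length(filt$nodes),
    n_filtered_edges = length(filt$edges),
    n_clustered_items = n_items,
    K = partition$K,
    quality = quality,
    n_significant_enrichments =
      if (!is.null(enrichment)) sum(enrichment$significant) else NULL,
    f_at_k = if (!is.null(pr_curve))
      pr_curve$f_score[pr_curve$k == round(config$k)] else NULL,
    n_predictions = if (!is.null(predictions)) nrow(predictions) else NULL)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_gdv(gdv, file.path(out_dir, "gdv.tsv"))
    write_partition(partition, file.path(out_dir, "partition.tsv"))
    if (!is.null(pr_curve))
      utils::write.table(pr_curve, file.path(out_dir, "pr_curve.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(predictions))
      utils::write.table(predictions, file.path(out_dir, "predictions.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")
  }
  list(partition = partition, quality = quality, enrichment = enrichment,
       pr_curve = pr_curve, predictions = predictions, summary = summary)
}
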