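# Hypergeometric cluster enrichment in pathogen-interacting (PI) proteins,
# leave-one-out cross-validation over an enrichment-threshold sweep,
# precision/recall/F-score, the size-preserving random-cluster baseline,
# and prediction of new protein-pathogen associations.

#' Eligible PI universe
#'
#' Applies the eligibility rules before any enrichment analysis: only
#' proteins with network degree above `min_degree` count (degrees measured
#' on the unfiltered graph), and only pathogens with at least two such
#' interactors are kept — with a single interactor a pathogen could never
#' be predicted for any other protein (enrichment needs two cluster
#' members) and would only depress recall.  The PI universe N is the set
#' of qualifying proteins that interact with at least one kept pathogen.
#'
#' @param graph Graph-like input (the full, unfiltered network).
#' @param pathogen_map Two-column data frame of (protein, pathogen)
#'   associations, or the path to such a TSV.
#' @param min_degree Degree cutoff (default 3; keep degree > 3).
#' @return List with `universe` (character vector N) and `map` (filtered
#'   association data frame with columns `protein`, `pathogen`).
#' @export
eligible_universe <- function(graph, pathogen_map, min_degree = 3L) {
  g <- as_ppi_graph(graph)
  map <- .as_pathogen_map(pathogen_map)
  deg <- igraph::degree(g)
  highdeg <- names(deg)[deg > min_degree]
  map <- map[map$protein %in% highdeg, , drop = FALSE]
  n_int <- table(map$pathogen)
  kept <- names(n_int)[n_int >= 2L]
  map <- map[map$pathogen %in% kept, , drop = FALSE]
  if (!nrow(map))
    stop("no pathogen has two or more eligible interactors; ",
         "universe is empty (check degrees and the association table)")
  list(universe = sort(unique(map$protein)), map = map)
}

.as_pathogen_map <- function(x) {
  if (is.character(x) && length(x) == 1L) x <- read_pathogen_map(x)
  stopifnot(is.data.frame(x), ncol(x) >= 2L)
  out <- data.frame(protein = as.character(x[[1]]),
                    pathogen = as.character(x[[2]]),
                    stringsAsFactors = FALSE)
  unique(out)
}

#' Upper-tail hypergeometric p-value
#'
#' Probability of observing `p` or more successes when drawing `C` items
#' without replacement from a population of `N` containing `P` successes
#' — the significance of finding `p` interactors of a pathogen among the
#' `C` universe proteins of a cluster.
#'
#' @param N Population size (PI universe).
#' @param P Successes in the population (the pathogen's interactors).
#' @param C Draws (the cluster's eligible proteins).
#' @param p Observed successes in the draw.
#' @return P(X >= p), in (0, 1]; `p = 0` gives 1.
#' @examples
#' hypergeom_pvalue(10, 5, 4, 4)   # 5/210
#' @export
hypergeom_pvalue <- function(N, P, C, p) {
  if (p < 0 || P > N || C > N || p > min(P, C))
    stop("inconsistent hypergeometric counts")
  stats::phyper(p - 1, P, N - P, C, lower.tail = FALSE)
}

#' Cluster-pathogen enrichment table
#'
#' For every (cluster, pathogen) pair: the cluster's eligible proteins C,
#' the number p of them interacting with the pathogen, the enrichment
#' p/C, and the hypergeometric p-value.  An enrichment is flagged
#' significant when its p-value is below `alpha` and the cluster has at
#' least two interactors (a single interactor cannot witness enrichment).
#'
#' @param partition An `egdv_partition` (node memberships are induced for
#'   edge partitions).
#' @param eligible Output of [eligible_universe()].
#' @param alpha Significance cutoff on the raw p-value (default 0.05; no
#'   multiple-testing correction is applied).
#' @return Data frame: `cluster`, `pathogen`, `N`, `P`, `C`, `p`,
#'   `enrichment`, `p_value`, `significant`.
#' @export
cluster_enrichment <- function(partition, eligible, alpha = 0.05) {
  universe <- eligible$universe
  N <- length(universe)
  sets <- lapply(partition_node_sets(partition), intersect, universe)
  sets <- sets[vapply(sets, length, 0L) > 0L]
  path_prot <- split(eligible$map$protein, eligible$map$pathogen)
  P_all <- vapply(path_prot, length, 0L)
  rows <- vector("list", length(sets) * length(path_prot))
  r <- 0L
  for (ci in seq_along(sets)) {
    members <- sets[[ci]]
    C <- length(members)
    for (pa in seq_along(path_prot)) {
      p <- length(intersect(members, path_prot[[pa]]))
      if (p == 0L) next
      r <- r + 1L
      rows[[r]] <- data.frame(
        cluster = names(sets)[ci], pathogen = names(path_prot)[pa],
        N = N, P = P_all[[pa]], C = C, p = p,
        enrichment = p / C,
        p_value = hypergeom_pvalue(N, P_all[[pa]], C, p))
    }
  }
  if (!r) return(data.frame(cluster = character(0), pathogen = character(0),
                            N = integer(0), P = integer(0), C = integer(0),
                            p = integer(0), enrichment = numeric(0),
                            p_value = numeric(0), significant = logical(0)))
  out <- do.call(rbind, rows[seq_len(r)])
  out$significant <- out$p_value < alpha & out$p >= 2L
  rownames(out) <- NULL
  out
}

#' F-score from precision and recall
#'
#' Harmonic mean `2 P R / (P + R)`, with the convention F = 0 when both
#' are 0.  Scale-free: percentages in give percentages out.
#'
#' @param precision,recall Same-scale accuracy values.
#' @return F-score on the input scale.
#' @examples
#' f_score(18, 30)   # 22.5 (percent)
#' @export
f_score <- function(precision, recall) {
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

# Per-candidate best qualifying enrichment (percent) under LOOCV hiding.
# Returns a data frame: protein, pathogen, known, best_enrichment.
.loocv_candidates <- function(partition, eligible, alpha = 0.05,
                              recompute_significance = TRUE) {
  universe <- eligible$universe
  N <- length(universe)
  sets <- lapply(partition_node_sets(partition), intersect, universe)
  sets <- sets[vapply(sets, length, 0L) > 0L]
  path_prot <- split(eligible$map$protein, eligible$map$pathogen)
  P_all <- vapply(path_prot, length, 0L)
  known_key <- paste(eligible$map$protein, eligible$map$pathogen)
  best <- new.env(parent = emptyenv())
  bump <- function(key, val) {
    cur <- get0(key, envir = best, ifnotfound = -Inf)
    if (val > cur) assign(key, val, envir = best)
  }
  for (ci in seq_along(sets)) {
    members <- sets[[ci]]
    C <- length(members)
    for (pa in seq_along(path_prot)) {
      P <- P_all[[pa]]
      hits <- intersect(members, path_prot[[pa]])
      p <- length(hits)
      if (p == 0L) next
      # unassociated members: full-data enrichment and significance
      if (p >= 2L && hypergeom_pvalue(N, P, C, p) < alpha) {
        e_non <- 100 * p / C
        for (prot in setdiff(members, hits))
          bump(paste(prot, names(path_prot)[pa]), e_non)
      }
      # associated members: hide the association (both p and P drop)
      p_h <- p - 1L
      P_h <- if (recompute_significance) P - 1L else P
      sig_h <- if (recompute_significance) {
        p_h >= 2L && hypergeom_pvalue(N, P_h, C, p_h) < alpha
      } else {
        p >= 2L && hypergeom_pvalue(N, P, C, p) < alpha
      }
      if (sig_h && p_h > 0L) {
        e_hid <- 100 * p_h / C
        for (prot in hits) bump(paste(prot, names(path_prot)[pa]), e_hid)
      }
    }
  }
  keys <- ls(best)
  vals <- vapply(keys, get, 0, envir = best)
  # candidates never touched by a qualifying cluster still count as
  # negatives/misses; collect them from the known associations
  miss <- setdiff(known_key, keys)
  all_keys <- c(keys, miss)
  parts <- strsplit(all_keys, " ", fixed = TRUE)
  data.frame(protein = vapply(parts, `[[`, "", 1L),
             pathogen = vapply(parts, `[[`, "", 2L),
             known = all_keys %in% known_key,
             best_enrichment = c(vals, rep(-Inf, length(miss))),
             stringsAsFactors = FALSE)
}

#' Precision-recall curve from leave-one-out cross-validation
#'
#' For every protein in a significantly enriched (cluster, pathogen) pair,
#' hides whether the protein is known to interact with the pathogen,
#' recomputes the cluster's enrichment and significance on the remaining
#' data, and predicts the interaction when the enrichment exceeds the
#' threshold k.  Sweeping k from 0% to 100% in 1% steps gives, at each k,
#' precision (true predictions among all predictions), recall (recovered
#' among all known associations) and their F-score.  Predictions are
#' aggregated per (protein, pathogen): the pair is predicted if any of the
#' protein's clusters qualifies.
#'
#' @inheritParams cluster_enrichment
#' @param ks Integer percent thresholds (default `0:100`).
#' @param recompute_significance Recompute the cluster's significance with
#'   the held-out association removed (default) instead of reusing the
#'   full-data significance.
#' @return Data frame: `k`, `tp`, `fp`, `fn`, `precision`, `recall`,
#'   `f_score` (precision/recall/F on the 0-1 scale).
#' @export
loocv_pr_curve <- function(partition, eligible, alpha = 0.05, ks = 0:100,
                           recompute_significance = TRUE) {
  cand <- .loocv_candidates(partition, eligible, alpha,
                            recompute_significance)
  n_known <- sum(cand$known)
  out <- data.frame(k = ks, tp = 0L, fp = 0L, fn = 0L,
                    precision = 0, recall = 0, f_score = 0)
  for (i in seq_along(ks)) {
    pred <- cand$best_enrichment > ks[i]
    tp <- sum(pred & cand$known)
    fp <- sum(pred & !cand$known)
    fn <- n_known - tp
    prec <- if (tp + fp == 0L) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0L) 0 else tp / (tp + fn)
    out[i, -1L] <- list(tp, fp, fn, prec, rec, f_score(prec, rec))
  }
  out
}

#' Random-cluster baseline F-scores
#'
#' Repeatedly reassigns nodes at random to clusters of the same sizes as
#' the data clusters (sampling without replacement within a cluster, so
#' overlapping memberships keep their multiplicity), reruns the LOOCV
#' sweep on each randomisation, and averages the F-scores per threshold.
#' Data clusters that beat this baseline carry real signal.
#'
#' @inheritParams loocv_pr_curve
#' @param runs Number of randomisation runs (default 100).
#' @param seed Integer seed (required; run r uses `seed + r - 1`).
#' @return Data frame `k`, `mean_f`, plus matrix attribute `"runs"` with
#'   the per-run F-scores.
#' @export
random_baseline <- function(partition, eligible, runs = 100L, seed,
                            alpha = 0.05, ks = 0:100,
                            recompute_significance = TRUE) {
  sizes <- vapply(partition_node_sets(partition), length, 0L)
  pool <- .default_universe(partition)
  fmat <- matrix(0, length(ks), runs)
  for (r in seq_len(runs)) {
    sets <- .with_seed(seed + r - 1L, lapply(sizes, function(s)
      sample(pool, min(s, length(pool)))))
    fmat[, r] <- loocv_pr_curve(.override_partition(sets), eligible,
                                alpha, ks, recompute_significance)$f_score
  }
  out <- data.frame(k = ks, mean_f = rowMeans(fmat))
  attr(out, "runs") <- fmat
  out
}

# A partition-like object backed directly by node sets (used for the
# random baseline, where clusters may overlap and share sampled nodes).
.override_partition <- function(sets) {
  names(sets) <- as.character(seq_along(sets))
  out <- list(assignment = NULL, K = length(sets), items = unique(unlist(sets)),
              kind = "node", node_sets = sets)
  class(out) <- "egdv_partition"
  out
}

#' Predict new protein-pathogen associations
#'
#' From every significantly enriched (cluster, pathogen) pair whose
#' enrichment exceeds `k` percent, predicts all eligible cluster proteins
#' not already associated with the pathogen.  Predictions are
#' deduplicated per (protein, pathogen), keeping the best supporting
#' enrichment.  A high k trades recall for confidence.
#'
#' @inheritParams cluster_enrichment
#' @param k Enrichment threshold in percent (strict inequality;
#'   default 66).
#' @param method Optional label recorded in the `methods` column, so that
#'   prediction sets from several clustering strategies can be merged with
#'   [merge_predictions()].
#' @return Data frame: `protein`, `pathogen`, `cluster`, `enrichment`,
#'   `p_value`, `methods`.
#' @export
predict_new <- function(partition, eligible, k = 66, alpha = 0.05,
                        method = "clustering") {
  enr <- cluster_enrichment(partition, eligible, alpha)
  enr <- enr[enr$significant & 100 * enr$enrichment > k, , drop = FALSE]
  universe <- eligible$universe
  sets <- lapply(partition_node_sets(partition), intersect, universe)
  path_prot <- split(eligible$map$protein, eligible$map$pathogen)
  rows <- list()
  for (i in seq_len(nrow(enr))) {
    members <- sets[[enr$cluster[i]]]
    new_prot <- setdiff(members, path_prot[[enr$pathogen[i]]])
    if (!length(new_prot)) next
    rows[[length(rows) + 1L]] <- data.frame(
      protein = new_prot, pathogen = enr$pathogen[i],
      cluster = enr$cluster[i], enrichment = enr$enrichment[i],
      p_value = enr$p_value[i], methods = method)
  }
  if (!length(rows))
    return(data.frame(protein = character(0), pathogen = character(0),
                      cluster = character(0), enrichment = numeric(0),
                      p_value = numeric(0), methods = character(0)))
  out <- do.call(rbind, rows)
  out <- out[order(out$protein, out$pathogen, -out$enrichment, out$p_value), ]
  out[!duplicated(out[c("protein", "pathogen")]), , drop = FALSE]
}

#' Merge prediction tables from several clustering strategies
#'
#' Deduplicates (protein, pathogen) predictions across methods, recording
#' every supporting method; predictions supported by several methods are
#' higher-confidence.
#'
#' @param prediction_list Named list of data frames from [predict_new()].
#' @return Data frame with a comma-separated `methods` column and
#'   `n_methods`.
#' @export
merge_predictions <- function(prediction_list) {
  if (!is.null(names(prediction_list)))
    prediction_list <- lapply(names(prediction_list), function(nm) {
      df <- prediction_list[[nm]]
      if (nrow(df)) df$methods <- nm
      df
    })
  all <- do.call(rbind, prediction_list)
  if (!nrow(all)) return(cbind(all, n_methods = integer(0)))
  key <- paste(all$protein, all$pathogen)
  methods <- vapply(split(all$methods, key), function(m)
    paste(sort(unique(m)), collapse = ","), "")
  first <- all[!duplicated(key), , drop = FALSE]
  first$methods <- methods[paste(first$protein, first$pathogen)]
  first$n_methods <- lengths(strsplit(first$methods, ","))
  rownames(first) <- NULL
  first
}
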