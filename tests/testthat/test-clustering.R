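sim_from <- function(items, pairs) {
  n <- length(items)
  S <- diag(n); dimnames(S) <- list(items, items)
  for (p in pairs) S[p[[1]], p[[2]]] <- S[p[[2]], p[[1]]] <- p[[3]]
  S
}

test_that("single linkage merges in forced order and cuts recover structure", {
  S <- sim_from(c("A", "B", "C"),
                list(list("A", "B", 0.9), list("A", "C", 0.1),
                     list("B", "C", 0.1)))
  d <- single_linkage(S)
  expect_equal(d$merge_sim, c(0.9, 0.1))
  p2 <- cut_dendrogram(d, 2)
  expect_equal(p2$assignment[["A"]], p2$assignment[["B"]])
  expect_false(p2$assignment[["A"]] == p2$assignment[["C"]])

  # two tight pairs
  S4 <- sim_from(c("A", "B", "C", "D"),
                 list(list("A", "B", 0.9), list("C", "D", 0.9),
                      list("A", "C", 0.05), list("A", "D", 0.05),
                      list("B", "C", 0.05), list("B", "D", 0.05)))
  d4 <- single_linkage(S4)
  p <- cut_dendrogram(d4, 2)
  expect_equal(p$assignment[["A"]], p$assignment[["B"]])
  expect_equal(p$assignment[["C"]], p$assignment[["D"]])
  expect_false(p$assignment[["A"]] == p$assignment[["C"]])

  expect_equal(cut_dendrogram(d4, 1)$K, 1L)
  expect_equal(cut_dendrogram(d4, 4)$K, 4L)
  expect_error(cut_dendrogram(d4, 0), "range")
  expect_error(cut_dendrogram(d4, 5), "range")
})

test_that("tied merge levels are cut as a single level", {
  S <- sim_from(c("A", "B", "C"),
                list(list("A", "B", 0.5), list("A", "C", 0.5),
                     list("B", "C", 0.5)))
  d <- single_linkage(S)
  p <- cut_dendrogram(d, 2)   # K = 2 falls inside the tie block
  expect_equal(p$K, 1L)
  expect_equal(p$requested_K, 2L)
  expect_equal(cut_dendrogram(d, 3)$K, 3L)
})

test_that("single linkage equals brute-force threshold clustering", {
  for (seed in 1:6) {
    n <- 8L
    S <- egdv:::.with_seed(seed, {
      M <- matrix(round(stats::runif(n * n), 2), n)
      M <- pmax(M, t(M)); diag(M) <- 1
      dimnames(M) <- list(letters[1:n], letters[1:n])
      M
    })
    d <- single_linkage(S)
    h <- d$hclust$height
    ends <- which(diff(c(h, Inf)) != 0)
    for (m in ends) {
      p <- cut_dendrogram(d, n - m)
      # components of the graph with similarity >= the merge level
      thr <- 1 - h[m]
      gt <- igraph::graph_from_adjacency_matrix(S >= thr - 1e-12,
                                                mode = "undirected",
                                                diag = FALSE)
      comp <- igraph::components(gt)$membership
      expect_equal(egdv:::.with_seed(NULL, mclust::adjustedRandIndex(
        p$assignment[letters[1:n]], comp)), 1)
    }
  }
})

test_that("partition density matches the closed forms", {
  tri <- toy_graph("triangle")
  p <- single_cluster_partition(edge_keys(tri))
  pd <- partition_density(p)
  expect_equal(pd$D, 1, tolerance = 1e-12)
  expect_equal(pd$per_cluster$D_C, 1)

  # single-edge cluster: density defined as 0
  p1 <- single_cluster_partition("a|b")
  expect_equal(partition_density(p1)$per_cluster$D_C, 0)

  # a clique's full edge set saturates the formula
  k5 <- toy_graph("clique5")
  expect_equal(partition_density(
    single_cluster_partition(edge_keys(k5)))$per_cluster$D_C, 1)
})

test_that("select_partition optimises its objective over all cut levels", {
  tri <- toy_graph("triangle")
  eg <- count_edge_gdv(tri)
  S <- edge_gdv_similarity_matrix(eg)
  d <- single_linkage(S)
  p <- select_partition(d, "max_density")
  expect_equal(p$K, 1L)
  expect_equal(partition_density(p)$D, 1)
  scan <- attr(p, "scan")
  expect_true(all(partition_density(p)$D >= scan$D))
  # a non-binding coverage cap changes nothing
  p2 <- select_partition(d, "max_density_cc_capped", cc_cap = 1.0)
  expect_equal(p2$assignment, p$assignment)
  expect_error(select_partition(d, "max_density_cc_capped"), "cc_cap")
  expect_error(select_partition(d, "best_overall_quality"), "annotations")
})

test_that("best_overall_quality recovers a planted annotated partition", {
  # two 4-cliques bridged by one edge; annotations follow the cliques
  g <- igraph::graph_from_edgelist(rbind(
    t(utils::combn(paste0("a", 1:4), 2)),
    t(utils::combn(paste0("b", 1:4), 2)),
    c("a1", "b1")), directed = FALSE)
  ann <- c(setNames(rep(list("TA"), 4), paste0("a", 1:4)),
           setNames(rep(list("TB"), 4), paste0("b", 1:4)))
  eg <- count_edge_gdv(g)
  S <- edge_gdv_similarity_matrix(eg, graph = g, adjacent_only = TRUE)
  d <- single_linkage(S)
  p <- select_partition(d, "best_overall_quality", annotations = ann,
                        node_universe = igraph::V(g)$name)
  sets <- partition_node_sets(p)
  big <- sets[order(-vapply(sets, length, 0L))][1:2]
  expect_setequal(sort(vapply(big, function(s)
    paste(sort(setdiff(s, c())), collapse = ","), "")),
    c("a1,a2,a3,a4", "b1,b2,b3,b4"))
})

test_that("k-medoids is reproducible, monotone and recovers separated blocks", {
  ten <- paste0("i", 1:10)
  S <- matrix(0.05, 10, 10, dimnames = list(ten, ten))
  S[1:5, 1:5] <- 0.9; S[6:10, 6:10] <- 0.9; diag(S) <- 1
  D <- 1 - S
  for (seed in 1:20) {
    p <- k_medoids(D, 2, seed = seed)
    expect_true(p$converged)
    expect_length(unique(p$assignment[1:5]), 1L)
    expect_length(unique(p$assignment[6:10]), 1L)
    expect_false(p$assignment[[1]] == p$assignment[[10]])
    expect_true(all(diff(p$cost_trace) <= 1e-12))
  }
  p1 <- k_medoids(D, 3, seed = 11)
  p2 <- k_medoids(D, 3, seed = 11)
  expect_identical(p1$assignment, p2$assignment)
  pk <- k_medoids(D, 10, seed = 1)
  expect_equal(pk$cost, 0)
  expect_error(k_medoids(D, 11, seed = 1), "exceeds")
})

test_that("the degree filter keeps the well-connected core", {
  g <- toy_graph("star5")   # hub degree 4, leaves degree 1
  f <- degree_filter(g, 3)
  expect_equal(f$nodes, igraph::V(g)$name[1])
  expect_length(f$edges, 0L)
  f0 <- degree_filter(g, 0)
  expect_setequal(f0$nodes, igraph::V(g)$name)
  expect_length(f0$edges, igraph::ecount(g))
  k5 <- toy_graph("clique5")
  f5 <- degree_filter(k5, 3)
  expect_length(f5$nodes, 5L)
  expect_length(f5$edges, 10L)
})
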