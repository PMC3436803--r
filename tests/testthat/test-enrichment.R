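# Small hand-built eligibility fixture: a 6-clique core so every protein
# passes the degree>3 rule, plus explicit association tables.
clique_graph <- function(n, prefix = "p") {
  g <- igraph::make_full_graph(n)
  igraph::V(g)$name <- paste0(prefix, seq_len(n))
  g
}

test_that("the eligible universe applies the degree and two-interactor rules", {
  g <- clique_graph(6)
  # star leaves have degree 1 and must not qualify
  g <- igraph::add_vertices(g, 2, name = c("low1", "low2"))
  g <- igraph::add_edges(g, c("p1", "low1", "p1", "low2"))
  map <- data.frame(
    protein = c("p1", "p2", "p3", "p4", "p5", "low1"),
    pathogen = c("X1", "X1", "X2", "X2", "X3", "X3"))
  elig <- eligible_universe(g, map, min_degree = 3)
  # X3's only high-degree interactor is p5 -> X3 dropped, p5 excluded
  expect_setequal(elig$universe, c("p1", "p2", "p3", "p4"))
  expect_setequal(unique(elig$map$pathogen), c("X1", "X2"))
  # all pathogens qualifying leaves the map unchanged
  map2 <- map[map$pathogen != "X3", ]
  elig2 <- eligible_universe(g, map2, min_degree = 3)
  expect_equal(nrow(elig2$map), nrow(map2))
  # nothing qualifying errors with a diagnostic
  expect_error(eligible_universe(g, data.frame(protein = "low1",
                                               pathogen = "X9"), 3),
               "universe is empty")
})

test_that("hypergeometric p-values match exhaustive enumeration", {
  expect_equal(hypergeom_pvalue(10, 5, 4, 0), 1)
  expect_equal(hypergeom_pvalue(10, 5, 4, 4), 5 / 210, tolerance = 1e-12)
  expect_error(hypergeom_pvalue(10, 5, 4, 5), "inconsistent")
  # oracle: enumerate all C-subsets of 1..N
  for (case in list(c(8, 3, 4, 2), c(10, 5, 4, 3), c(12, 6, 5, 1))) {
    N <- case[1]; P <- case[2]; C <- case[3]; p <- case[4]
    subsets <- utils::combn(N, C)
    hits <- colSums(subsets <= P)   # successes are items 1..P
    expect_equal(hypergeom_pvalue(N, P, C, p), mean(hits >= p),
                 tolerance = 1e-12)
  }
  # monotone in p
  pv <- vapply(0:4, function(p) hypergeom_pvalue(10, 5, 4, p), 0)
  expect_true(all(diff(pv) <= 0))
})

test_that("F-score is the harmonic mean with the zero convention", {
  expect_equal(f_score(18, 30), 22.5)
  expect_equal(f_score(0.3, 0.3), 0.3)
  expect_equal(f_score(0, 0), 0)
})

test_that("cluster enrichment flags significant pathogen concentrations", {
  uni <- paste0("p", 1:20)
  map <- data.frame(protein = c("p1", "p2", "p3", "p4"),
                    pathogen = c("X", "X", "Y", "Y"))
  elig <- list(universe = uni, map = map)
  p <- egdv:::.override_partition(list(c("p1", "p2", "p5"), uni[6:20]))
  enr <- cluster_enrichment(p, elig)
  row <- enr[enr$cluster == "1" & enr$pathogen == "X", ]
  expect_equal(row$C, 3L); expect_equal(row$p, 2L)
  expect_equal(row$enrichment, 2 / 3, tolerance = 1e-12)
  expect_equal(row$p_value, hypergeom_pvalue(20, 2, 3, 2))
  expect_true(row$significant)
})

test_that("LOOCV precision-recall behaves over the threshold sweep", {
  fix <- planted_fixture(seed = 2)
  elig <- eligible_universe(fix$graph, fix$pathogen_map, 3)
  blocks <- egdv:::.blocks_of(fix$graph)
  p <- egdv:::.override_partition(split(names(blocks), blocks))
  pr <- loocv_pr_curve(p, elig)
  expect_equal(pr$k, 0:100)
  # recall never increases with k; the association count is conserved
  expect_true(all(diff(pr$recall) <= 1e-12))
  expect_equal(unique(pr$tp + pr$fn), nrow(elig$map))
  expect_true(all(pr$precision >= 0 & pr$precision <= 1))
  expect_true(all(pr$f_score >= 0 & pr$f_score <= 1))
  expect_equal(pr$f_score[pr$k == 100], 0)   # enrichment <= 100 < strict
  # with planted modules the curve carries real signal at mid-range k
  expect_gt(max(pr$f_score), 0)
})

test_that("the random baseline is reproducible and weaker than planted clusters", {
  fix <- planted_fixture(seed = 2)
  elig <- eligible_universe(fix$graph, fix$pathogen_map, 3)
  blocks <- egdv:::.blocks_of(fix$graph)
  p <- egdv:::.override_partition(split(names(blocks), blocks))
  b1 <- random_baseline(p, elig, runs = 3, seed = 10)
  b2 <- random_baseline(p, elig, runs = 3, seed = 10)
  expect_equal(b1, b2)
  pr <- loocv_pr_curve(p, elig)
  b <- random_baseline(p, elig, runs = 10, seed = 11)
  mid <- pr$k %in% 40:80
  expect_gt(mean(pr$f_score[mid]), mean(b$mean_f[mid]))
})

test_that("predict_new emits only unassociated members of enriched clusters", {
  uni <- paste0("p", 1:20)
  map <- data.frame(protein = c("p1", "p2", "p4", "p5"),
                    pathogen = c("X", "X", "Y", "Y"))
  elig <- list(universe = uni, map = map)
  p <- egdv:::.override_partition(list(c("p1", "p2", "p3"),
                                       c("p4", "p5"), uni[6:20]))
  # cluster 1: 2/3 with X (66.7% > 66, significant) -> predict p3
  pred <- predict_new(p, elig, k = 66)
  expect_equal(nrow(pred), 1L)
  expect_equal(pred$protein, "p3")
  expect_equal(pred$pathogen, "X")
  # cluster 2 is 100% enriched for Y: nothing left to predict
  expect_false(any(pred$pathogen == "Y"))
  # the strict threshold empties predictions at k = 100
  expect_equal(nrow(predict_new(p, elig, k = 100)), 0L)
})

test_that("multi-method predictions are merged with provenance", {
  a <- data.frame(protein = c("p1", "p2"), pathogen = "X",
                  cluster = "1", enrichment = 0.8, p_value = 0.01,
                  methods = "m")
  b <- data.frame(protein = "p2", pathogen = "X",
                  cluster = "7", enrichment = 0.7, p_value = 0.02,
                  methods = "m")
  merged <- merge_predictions(list(`edge-hie` = a, `node-km` = b))
  expect_equal(nrow(merged), 2L)
  p2 <- merged[merged$protein == "p2", ]
  expect_equal(p2$methods, "edge-hie,node-km")
  expect_equal(p2$n_methods, 2L)
})
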