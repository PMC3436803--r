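node_partition <- function(...) {
  sets <- list(...)
  egdv:::.override_partition(sets)
}

test_that("cluster coverage counts nodes in non-trivial clusters", {
  uni <- paste0("n", 1:10)
  p <- node_partition(uni[1:4], uni[5:6], uni[7:8], uni[9:10])
  expect_equal(cluster_coverage(p, uni), 0.4)
  p_all <- node_partition(uni[1:5], uni[6:10])
  expect_equal(cluster_coverage(p_all, uni), 1)
  p_singletons <- egdv:::.override_partition(as.list(uni))
  expect_equal(cluster_coverage(p_singletons, uni), 0)
  expect_error(cluster_coverage(p, character(0)), "empty")
})

test_that("overlap coverage averages non-trivial memberships", {
  uni <- paste0("n", 1:5)
  # one node in 3 non-trivial clusters, four nodes in 1 each
  p <- node_partition(c("n1", "n2", "n3"), c("n1", "n4", "n5"),
                      c("n1", "n2", "n4"))
  counts <- c(3, 2, 1, 2, 1)   # n1..n5 memberships
  expect_equal(overlap_coverage(p, uni), mean(counts))
  disjoint <- node_partition(uni[1:3], uni[4:5])   # second is trivial
  expect_equal(overlap_coverage(disjoint, uni), 3 / 5)
})

test_that("cluster quality is the intra/overall annotation-similarity ratio", {
  ann <- list(n1 = "A", n2 = "A", n3 = "A", n4 = "B")
  p <- node_partition(c("n1", "n2"), c("n3", "n4"))
  # intra pairs: (n1,n2)=1, (n3,n4)=0 -> mean 1/2
  # all pairs: three 1s, three 0s -> mean 1/2
  expect_equal(cluster_quality(p, ann, node_universe = names(ann)), 1)
  p2 <- node_partition(c("n1", "n2"), c("n3"), c("n4"))
  # intra: (n1,n2)=1 -> 1; all: 3/6
  expect_equal(cluster_quality(p2, ann, node_universe = names(ann)), 2)
  # identical annotations everywhere: any grouping gives 1
  ann_same <- list(n1 = "A", n2 = "A", n3 = "A", n4 = "A")
  expect_equal(cluster_quality(p, ann_same, node_universe = names(ann_same)), 1)
  # one big cluster: numerator = denominator
  p_one <- node_partition(names(ann))
  expect_equal(cluster_quality(p_one, ann, node_universe = names(ann)), 1)
  # no annotated intra-cluster pairs -> undefined
  expect_message(
    out <- cluster_quality(node_partition("n1", "n2"), ann,
                           node_universe = names(ann)),
    "undefined")
  expect_true(is.na(out))
})

test_that("overlap quality is the mutual information of term and cluster counts", {
  # constant cluster count -> 0 bits
  uni <- paste0("n", 1:4)
  ann <- list(n1 = "A", n2 = c("A", "B"), n3 = "A", n4 = c("A", "B"))
  p_const <- node_partition(uni, uni)   # every node in 2 clusters
  expect_equal(overlap_quality(p_const, ann, uni), 0)
  # term count == cluster count, two equiprobable values -> 1 bit
  p_match <- node_partition(c("n1", "n3", "n2"), c("n2", "n4", "n1"))
  # memberships: n1 2, n2 2, n3 1, n4 1 -- align terms to match
  ann2 <- list(n1 = c("A", "B"), n2 = c("A", "B"), n3 = "A", n4 = "A")
  expect_equal(overlap_quality(p_match, ann2, uni), 1)
  # MI is never negative
  for (seed in 1:5) {
    sets <- egdv:::.with_seed(seed, replicate(3, sample(uni, 3), simplify = FALSE))
    expect_gte(overlap_quality(egdv:::.override_partition(sets), ann, uni), 0)
  }
})

test_that("normalisation scores the best method at 1 per measure, overall <= 4", {
  r1 <- list(cc = 0.5, oc = 1, cq = 2, oq = 0.2)
  r2 <- list(cc = 1.0, oc = 1, cq = 1, oq = 0.1)
  scored <- normalize_and_score(list(r1, r2))
  expect_equal(scored[[1]]$overall, 3.5)
  expect_equal(scored[[2]]$overall, 3.0)
  expect_equal(unname(scored[[1]]$normalized["cq"]), 1)
  ident <- normalize_and_score(list(r1, r1))
  expect_equal(ident[[1]]$overall, 4)
  expect_equal(ident[[2]]$overall, 4)
  # a measure with max 0 contributes nothing
  z1 <- list(cc = 0, oc = 0, cq = 1, oq = 0)
  z2 <- list(cc = 0, oc = 0, cq = 2, oq = 0)
  sz <- normalize_and_score(list(z1, z2))
  expect_equal(sz[[1]]$overall, 0.5)
  expect_equal(sz[[2]]$overall, 1)
  expect_error(normalize_and_score(list(r1)), "two")
})

test_that("quality_report bundles the four measures for real partitions", {
  fix <- planted_fixture(seed = 3)
  g <- fix$graph
  blocks <- egdv:::.blocks_of(g)
  sets <- split(names(blocks), blocks)
  p <- egdv:::.override_partition(sets)
  rep <- quality_report(p, fix$annotations, node_universe = names(blocks))
  expect_equal(rep$cc, 1)          # every block has >= 3 nodes
  expect_equal(rep$oc, 1)          # disjoint cover
  expect_gt(rep$cq, 1)             # planted annotations are block-coherent
  expect_gte(rep$oq, 0)
})
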