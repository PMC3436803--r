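test_that("toy generators produce the named graphs", {
  tri <- make_graph_fixture("triangle")
  expect_equal(igraph::vcount(tri), 3L)
  expect_equal(igraph::ecount(tri), 3L)
  p4 <- make_graph_fixture("path", n = 4)
  expect_equal(igraph::degree(p4), c(p001 = 1, p002 = 2, p003 = 2, p004 = 1))
  expect_equal(igraph::ecount(make_graph_fixture("clique", n = 5)), 10L)
})

test_that("generators are seed-deterministic down to the written files", {
  g1 <- make_graph_fixture("planted_partition", seed = 5)
  g2 <- make_graph_fixture("planted_partition", seed = 5)
  expect_identical(igraph::as_edgelist(g1), igraph::as_edgelist(g2))
  a1 <- make_annotations(g1, seed = 6)
  expect_identical(a1, make_annotations(g2, seed = 6))
  m1 <- make_pathogen_map(g1, seed = 7)
  expect_identical(m1, make_pathogen_map(g2, seed = 7))
  d1 <- file.path(tempdir(), "fixA"); d2 <- file.path(tempdir(), "fixB")
  write_fixture(d1, g1, a1, m1)
  write_fixture(d2, g2, make_annotations(g2, seed = 6),
                make_pathogen_map(g2, seed = 7))
  for (f in c("edges.tsv", "annotations.tsv", "pathogens.tsv", "truth.tsv"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("uniform random graphs realise the requested density", {
  dens <- vapply(1:30, function(seed) {
    g <- make_graph_fixture("gnp", n = 20, p = 0.2, seed = seed)
    igraph::ecount(g) / choose(20, 2)
  }, 0)
  se <- sqrt(0.2 * 0.8 / (choose(20, 2) * 30))
  expect_lt(abs(mean(dens) - 0.2), 3 * se)
})

test_that("planted-partition blocks are internally connected and recoverable", {
  single_comp <- 0L; total <- 0L
  for (seed in 1:20) {
    g <- make_graph_fixture("planted_partition", seed = seed)
    expect_true(igraph::is_simple(g))
    blocks <- egdv:::.blocks_of(g)
    expect_equal(as.vector(table(blocks)), rep(8L, 4L))
    for (b in unique(blocks)) {
      sub <- igraph::induced_subgraph(g, names(blocks)[blocks == b])
      total <- total + 1L
      if (igraph::components(sub)$no == 1L) single_comp <- single_comp + 1L
    }
  }
  expect_gt(single_comp / total, 0.9)
})

test_that("planted annotations concentrate the dominant term by purity", {
  g <- make_graph_fixture("planted_partition", seed = 8)
  blocks <- egdv:::.blocks_of(g)
  ann <- make_annotations(g, purity = 1, extra_rate = 0, seed = 9)
  for (v in names(blocks))
    expect_equal(ann[[v]], paste0("T", blocks[[v]]))
  # planted partition beats a random same-size partition on CQ
  p_true <- egdv:::.override_partition(split(names(blocks), blocks))
  p_rand <- egdv:::.override_partition(
    egdv:::.with_seed(10, split(sample(names(blocks)), blocks)))
  ann2 <- make_annotations(g, purity = 0.9, seed = 11)
  cq_true <- cluster_quality(p_true, ann2, node_universe = names(blocks))
  cq_rand <- cluster_quality(p_rand, ann2, node_universe = names(blocks))
  expect_gt(cq_true, cq_rand)
})

test_that("planted pathogen modules align with their home blocks", {
  g <- make_graph_fixture("planted_partition", seed = 12)
  blocks <- egdv:::.blocks_of(g)
  map <- make_pathogen_map(g, n_pathogens = 4, within_fraction = 1,
                           n_interactors = 5, seed = 13)
  # confinement to the home block
  for (x in unique(map$pathogen)) {
    prot <- map$protein[map$pathogen == x]
    expect_length(unique(blocks[prot]), 1L)
  }
  # every pathogen survives the eligibility rules
  elig <- eligible_universe(g, map, 3)
  expect_setequal(unique(elig$map$pathogen), unique(map$pathogen))
  # block clusters give each pathogen its minimal p-value at home
  p <- egdv:::.override_partition(split(names(blocks), blocks))
  enr <- cluster_enrichment(p, elig)
  for (x in unique(elig$map$pathogen)) {
    home <- as.character(unique(blocks[map$protein[map$pathogen == x]]))
    sub <- enr[enr$pathogen == x, ]
    expect_equal(sub$cluster[which.min(sub$p_value)], home)
  }
})
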