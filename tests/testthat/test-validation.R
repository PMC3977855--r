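p3 <- graph_from_edges(rbind(c("a", "b"), c("b", "c")))

test_that("extreme_node_sets finds ties, constants and histogram fallbacks", {
  deg <- degree_centrality(p3)
  ex <- extreme_node_sets(deg)
  expect_identical(ex$argmax_nodes, "b")
  expect_setequal(ex$argmin_nodes, c("a", "c"))
  expect_equal(ex$n_min, 2L)
  expect_false(ex$constant)

  const <- extreme_node_sets(c(x = 1, y = 1, z = 1))
  expect_true(const$constant)
  expect_equal(const$n_max, 3L)
  expect_equal(const$hist_n_min, 3L)

  # counts invariant under positive scaling and relabeling
  v <- c(a = 0.1, b = 0.5, c = 0.5, d = 0.9)
  for (s in c(1, 7, 1e6)) {
    ex2 <- extreme_node_sets(v * s)
    expect_equal(ex2$n_max, 1L)
    expect_equal(ex2$n_min, 1L)
  }
  relab <- setNames(unname(v), c("w", "x", "y", "z"))
  expect_equal(extreme_node_sets(relab)$n_max, extreme_node_sets(v)$n_max)

  # near-ties within 1e-9 after 12-significant-digit rounding count as tied
  expect_equal(extreme_node_sets(c(a = 1, b = 1 + 1e-13))$n_max, 2L)
})

test_that("rank_correlation is a valid tie-aware correlation matrix", {
  g <- rg_connected(20, 0.2, 7)
  prof <- compute_profile(g)
  rc <- rank_correlation(prof)
  expect_equal(rc$method, "kendall")
  expect_equal(unname(diag(rc$entries)), rep(1, 5))
  expect_equal(rc$entries, t(rc$entries), tolerance = 1e-12)
  expect_true(all(rc$entries >= -1 - 1e-12 & rc$entries <= 1 + 1e-12))
  expect_identical(rc$flipped, "eccentricity")

  rs <- rank_correlation(prof, method = "spearman")
  expect_equal(unname(diag(rs$entries)), rep(1, 5))

  # after the eccentricity flip, closeness and eccentricity rank the same way
  # on a star-like graph (centre closest AND least eccentric)
  hub <- planted_hub(10, rewire = 0.2, seed = 3)$graph
  rc2 <- rank_correlation(compute_profile(hub))
  expect_gt(rc2$entries["closeness", "eccentricity"], 0)
})

test_that("rank_correlation needs at least 3 shared nodes", {
  tiny <- graph_from_edges(rbind(c("a", "b")))
  prof <- compute_profile(tiny)
  expect_error(rank_correlation(prof), "fewer than 3")
})

test_that("top_k_overlap behaves at the boundaries", {
  g <- rg_connected(12, 0.3, 11)
  prof <- compute_profile(g)
  full <- top_k_overlap(prof, k = n_nodes(g))
  expect_true(all(full$entries == 1))
  expect_equal(unname(diag(top_k_overlap(prof, k = 3)$entries)), rep(1, 5))
  expect_error(top_k_overlap(prof, k = 0), "between 1 and")

  hub <- compute_profile(planted_hub(10, rewire = 0.1, seed = 2)$graph)
  t1 <- top_k_overlap(hub, k = 1)
  expect_equal(t1$entries["degree", "eigenvector"], 1)
  expect_identical(t1$top$degree, "hub")

  br <- compute_profile(planted_bridge(4)$graph)
  tb <- top_k_overlap(br, k = 1)
  expect_identical(tb$top$betweenness, "broker")
  expect_false(identical(tb$top$degree, "broker"))  # broker degree is only 2
})

test_that("ground-truth scoring counts hits and reciprocal ranks", {
  hub <- planted_hub(10, rewire = 0.1, seed = 4)
  prof <- compute_profile(hub$graph)
  rep1 <- score_against_ground_truth(prof, hub, k = 1)
  sc <- rep1$scores
  expect_equal(sc$hits[sc$measure == "degree"], 1L)
  expect_equal(sc$reciprocal_rank[sc$measure == "degree"], 1)
  expect_true(all(sc$hits <= pmin(rep1$k, length(hub$influential))))

  # hits monotone non-decreasing in k
  hits_k <- vapply(1:6, function(k) {
    s <- score_against_ground_truth(prof, hub, k = k)$scores
    sum(s$hits)
  }, numeric(1))
  expect_true(all(diff(hits_k) >= 0))

  empty <- annotated_graph(hub$graph, character(0), "no truth")
  repe <- score_against_ground_truth(prof, empty)
  expect_null(repe$scores)
  expect_match(repe$warnings, "empty ground-truth")
})
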