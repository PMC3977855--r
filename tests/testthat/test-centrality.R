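p3 <- graph_from_edges(rbind(c("a", "b"), c("b", "c")))
k4 <- graph_from_edges(t(utils::combn(c("a", "b", "c", "d"), 2)))
c4 <- graph_from_edges(rbind(c("a","b"), c("b","c"), c("c","d"), c("d","a")))

test_that("closed forms: P3, K4, C4, K1,4", {
  expect_equal(degree_centrality(p3)$scores, c(a = 0.5, b = 1, c = 0.5))
  expect_equal(betweenness_centrality(p3)$scores, c(a = 0, b = 1, c = 0))
  expect_equal(closeness_centrality(p3)$scores, c(a = 1/3, b = 1/2, c = 1/3))
  expect_equal(eccentricity_centrality(p3)$scores, c(a = 2, b = 1, c = 2))
  e3 <- eigenvector_centrality(p3)
  expect_equal(e3$eigenvalue, sqrt(2), tolerance = 1e-9)
  expect_equal(unname(e3$vector$scores), c(1, sqrt(2), 1) / 2, tolerance = 1e-9)

  expect_equal(unname(degree_centrality(k4)$scores), rep(1, 4))
  expect_equal(unname(closeness_centrality(k4)$scores), rep(1/3, 4))
  expect_equal(unname(eccentricity_centrality(k4)$scores), rep(1, 4))
  e4 <- eigenvector_centrality(k4)
  expect_equal(e4$eigenvalue, 3, tolerance = 1e-9)
  expect_equal(unname(e4$vector$scores), rep(0.5, 4), tolerance = 1e-9)

  # C4 is bipartite: resolved by the damping shift (or converges directly),
  # and the dominant eigenvector is still uniform with lambda = 2
  ec4 <- eigenvector_centrality(c4)
  expect_equal(ec4$eigenvalue, 2, tolerance = 1e-9)
  expect_equal(unname(ec4$vector$scores), rep(0.5, 4), tolerance = 1e-9)
  expect_true(ec4$residual <= 1e-8)

  star <- planted_hub(4, rewire = 0, seed = 1)$graph
  expect_equal(betweenness_centrality(star)$scores[["hub"]], 6)
  es <- eigenvector_centrality(star)
  expect_equal(es$eigenvalue, 2, tolerance = 1e-9)
  expect_equal(es$vector$scores[["hub"]], 1 / sqrt(2), tolerance = 1e-9)
  expect_equal(es$shift, 1)  # uniform start oscillates on this bipartite graph
})

test_that("every measure matches its brute-force oracle on random graphs", {
  cases <- expand.grid(seed = 1:20, p = c(0.25, 0.4))
  for (i in seq_len(nrow(cases))) {
    g <- rg(sample(4:10, 1), cases$p[i], cases$seed[i])
    if (n_edges(g) == 0L) next
    expect_equal(degree_centrality(g)$scores, o_degree(g), tolerance = 1e-10)
    expect_equal(betweenness_centrality(g)$scores, o_betweenness(g),
                 tolerance = 1e-9)
    lcc_ok <- length(o_lcc_nodes(g)) >= 2
    if (lcc_ok) {
      clo <- suppressWarnings(closeness_centrality(g))$scores
      expect_equal(clo[sort(names(clo))], o_closeness(g)[sort(names(clo))],
                   tolerance = 1e-10)
      ecc <- suppressWarnings(eccentricity_centrality(g))$scores
      expect_equal(ecc[sort(names(ecc))], o_eccentricity(g)[sort(names(ecc))])
    }
    er <- eigenvector_centrality(g)
    # defining property always holds...
    expect_true(er$residual <= 1e-8)
    expect_true(all(er$vector$scores >= 0))
    expect_equal(sum(er$vector$scores^2), 1, tolerance = 1e-10)
    # ...and the vector itself matches dense eigendecomposition when the
    # dominant eigenvalue is simple (otherwise it is not uniquely defined)
    A <- o_adj_matrix(g)
    ev <- sort(eigen(A, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    if (ev[1] - ev[2] > 1e-6) {
      expect_equal(er$vector$scores, o_eigenvector(g), tolerance = 1e-7)
    }
  }
})

test_that("vertex-transitive graphs get constant vectors", {
  ring <- function(n) {
    labs <- sprintf("v%d", 1:n)
    graph_from_edges(cbind(labs, labs[c(2:n, 1)]))
  }
  for (g in list(ring(5), ring(6), graph_from_edges(t(utils::combn(sprintf("v%d", 1:5), 2))))) {
    prof <- compute_profile(g)
    for (m in centrality_measures()) {
      s <- prof$vectors[[m]]$scores
      expect_lt(max(s) - min(s), 1e-9)
    }
  }
})

test_that("relabeling nodes permutes every vector identically", {
  g <- rg_connected(9, 0.35, 5)
  perm <- setNames(sprintf("z%02d", sample(9)), g$nodes)
  g2 <- graph_from_edges(cbind(perm[g$edges[, 1]], perm[g$edges[, 2]]),
                         nodes = unname(perm[g$nodes]))
  p1 <- compute_profile(g)
  p2 <- compute_profile(g2)
  for (m in centrality_measures()) {
    s1 <- p1$vectors[[m]]$scores
    s2 <- p2$vectors[[m]]$scores
    expect_equal(unname(s2[perm[names(s1)]]), unname(s1), tolerance = 1e-7)
  }
})

test_that("structural identities hold on random graphs", {
  for (seed in 1:10) {
    g <- rg_connected(10, 0.3, seed + 100)
    # sum of normalised degrees x (n-1) = 2M
    expect_equal(sum(degree_centrality(g)$scores) * (n_nodes(g) - 1),
                 2 * n_edges(g))
    ecc <- eccentricity_centrality(g)$scores
    expect_true(all(min(ecc) <= ecc & ecc <= max(ecc)))
    er <- eigenvector_centrality(g)
    d <- node_degrees(g)
    expect_gte(er$eigenvalue, mean(d) - 1e-9)
    expect_lte(er$eigenvalue, max(d) + 1e-9)
  }
})

test_that("planted structures are recovered by the right measures", {
  for (seed in 1:20) {
    hub <- planted_hub(10, rewire = 0.1, seed = seed)
    pd <- degree_centrality(hub$graph)
    pe <- eigenvector_centrality(hub$graph)$vector
    expect_identical(extreme_node_sets(pd)$argmax_nodes, "hub")
    expect_identical(extreme_node_sets(pe)$argmax_nodes, "hub")

    br <- planted_bridge(3 + seed %% 4)
    pb <- betweenness_centrality(br$graph)
    expect_identical(extreme_node_sets(pb)$argmax_nodes, "broker")
  }
})

test_that("disconnected input restricts the distance measures, with warning", {
  g <- graph_from_edges(rbind(c("a","b"), c("b","c"), c("x","y")))
  expect_warning(clo <- closeness_centrality(g), "largest connected component")
  expect_setequal(names(clo$scores), c("a", "b", "c"))
  expect_setequal(clo$component, c("a", "b", "c"))
  deg <- degree_centrality(g)
  expect_equal(length(deg$scores), 5L)
  prof <- suppressWarnings(compute_profile(g))
  expect_setequal(prof$component, c("a", "b", "c"))
})

test_that("degenerate inputs error cleanly", {
  solo <- graph_from_edges(NULL, nodes = "a")
  expect_error(degree_centrality(solo), "at least 2")
  expect_error(closeness_centrality(solo), "single-node")
  expect_error(eccentricity_centrality(solo), "single-node")
  expect_error(eigenvector_centrality(solo), "at least one edge")
})
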