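test_that("graph construction collapses to an undirected simple graph", {
  g <- graph_from_edges(rbind(c("a", "b"), c("b", "a"), c("a", "b")))
  expect_equal(n_nodes(g), 2L)
  expect_equal(n_edges(g), 1L)
  expect_warning(graph_from_edges(rbind(c("a", "a"), c("a", "b")), warn = TRUE),
                 "self-loop")
  g2 <- suppressWarnings(graph_from_edges(rbind(c("a", "a"), c("a", "b")),
                                          warn = TRUE))
  expect_equal(n_edges(g2), 1L)
  expect_equal(sum(node_degrees(g)), 2L * n_edges(g))
})

test_that("read_gml parses the benchmark subset", {
  doc <- 'graph [\n node [ id 1 ]\n node [ id 2 ]\n edge [ source 1 target 2 ]\n]'
  g <- read_gml(doc)
  expect_equal(n_nodes(g), 2L)
  expect_equal(n_edges(g), 1L)
  expect_setequal(g$nodes, c("1", "2"))

  # labels win over ids; reciprocal edges collapse with a warning
  doc2 <- paste(
    "graph [",
    '  node [ id 0 label "alpha" ]',
    '  node [ id 1 label "beta" ]',
    "  edge [ source 0 target 1 ]",
    "  edge [ source 1 target 0 ]",
    "]", sep = "\n")
  expect_warning(g2 <- read_gml(doc2), "collapsed")
  expect_equal(n_edges(g2), 1L)
  expect_setequal(g2$nodes, c("alpha", "beta"))

  expect_warning(
    read_gml("graph [ directed 1\n node [ id 1 ]\n node [ id 2 ]\n edge [ source 1 target 2 ] ]"),
    "directed")
})

test_that("read_gml rejects malformed input with line information", {
  expect_error(read_gml("graph [\n node [ id 1\n]"), "line")
  expect_error(
    read_gml("graph [ node [ id 1 ] edge [ source 1 target 9 ] ]"),
    "unknown node id")
  expect_error(read_gml("graph [ node [ label \"x\" ] ]"), "without 'id'")
})

test_that("read_edge_list handles comments, isolates and dedup", {
  g <- read_edge_list("a b\nb c")
  expect_equal(n_nodes(g), 3L)
  expect_equal(n_edges(g), 2L)
  g2 <- suppressWarnings(read_edge_list("a b\nb a\na b"))
  expect_equal(n_nodes(g2), 2L)
  expect_equal(n_edges(g2), 1L)
  g3 <- read_edge_list("# comment\na b\n\nlonely")
  expect_true("lonely" %in% g3$nodes)
  expect_equal(n_edges(g3), 1L)
  expect_error(read_edge_list("a b c"), "line 1")
})

test_that("bfs_distances matches the cubic all-pairs oracle", {
  # path graph: exact hops; unreachable absent
  p3 <- graph_from_edges(rbind(c("a", "b"), c("b", "c")))
  expect_equal(bfs_distances(p3, "a"), c(a = 0L, b = 1L, c = 2L),
               ignore_attr = TRUE)
  two <- graph_from_edges(NULL, nodes = c("a", "b"))
  expect_equal(names(bfs_distances(two, "a")), "a")
  expect_error(bfs_distances(p3, "zz"), "unknown source")

  for (seed in 1:30) {
    g <- rg(sample(4:12, 1), 0.3, seed)
    D <- o_floyd(g)
    src <- sample(g$nodes, 1)
    d <- bfs_distances(g, src)
    expect_equal(sort(names(d)), sort(names(which(is.finite(D[src, ])))))
    expect_equal(unname(d[names(d)]), unname(D[src, names(d)]))
  }
})

test_that("count_geodesics agrees with explicit path enumeration", {
  c4 <- graph_from_edges(rbind(c("a","b"), c("b","c"), c("c","d"), c("d","a")))
  gc <- count_geodesics(c4)
  expect_equal(gc$sigma["a", "c"], 2)
  p3 <- graph_from_edges(rbind(c("a","b"), c("b","c")))
  expect_equal(count_geodesics(p3)$through["a", "c", "b"], 1)

  for (seed in 1:20) {
    g <- rg(sample(5:10, 1), 0.35, seed)
    mine <- count_geodesics(g)
    oracle <- o_enumerate(g)
    expect_equal(mine$sigma, oracle$sigma)
    expect_equal(mine$through, oracle$through)
  }
})

test_that("largest_connected_component matches union-find", {
  k3 <- graph_from_edges(rbind(c("a","b"), c("b","c"), c("a","c")),
                         nodes = c("a", "b", "c", "isolate"))
  lcc <- largest_connected_component(k3)
  expect_setequal(lcc$nodes, c("a", "b", "c"))

  conn <- rg_connected(8, 0.5, 3)
  expect_equal(largest_connected_component(conn)$nodes, conn$nodes)

  for (seed in 1:15) {
    g <- rg(50, 0.02, seed)
    comp <- o_components(g)
    expect_equal(length(comp), 50L)
    lcc <- largest_connected_component(g)
    expect_equal(n_nodes(lcc), max(table(comp)))
    expect_setequal(lcc$nodes, names(comp)[comp == comp[[lcc$nodes[1]]]])
  }
})

test_that("annotated GML round-trips node and edge sets", {
  one <- graph_from_edges(NULL, nodes = "solo")
  # single node: degree normalisation undefined, so write without profile
  txt <- write_gml(one)
  expect_equal(read_gml(txt)$nodes, "solo")

  k4 <- graph_from_edges(t(utils::combn(c("a","b","c","d"), 2)))
  prof <- compute_profile(k4, id = "k4")
  txt <- write_annotated_gml(k4, prof)
  expect_true(any(grepl("degree_c 1", txt)))
  back <- read_gml(txt)
  expect_setequal(back$nodes, k4$nodes)
  expect_equal(back$edges, k4$edges)

  for (seed in 1:10) {
    g <- rg(sample(c(20, 60, 100), 1), 0.08, seed + 40)
    if (n_nodes(largest_connected_component(g)) < 2) next
    prof <- suppressWarnings(compute_profile(g))
    back <- read_gml(write_annotated_gml(g, prof))
    expect_setequal(back$nodes, g$nodes)
    expect_equal(back$edges, g$edges)
  }
})

test_that("collapsing a directed multigraph loses no adjacency", {
  set.seed(11)
  for (rep in 1:10) {
    n <- 8
    labs <- letters[1:n]
    arcs <- cbind(sample(labs, 40, TRUE), sample(labs, 40, TRUE))
    arcs <- arcs[arcs[, 1] != arcs[, 2], , drop = FALSE]
    g <- suppressWarnings(graph_from_edges(arcs, warn = TRUE))
    key <- paste(g$edges[, 1], g$edges[, 2])
    for (r in seq_len(nrow(arcs))) {
      expect_true(paste(min(arcs[r, ]), max(arcs[r, ])) %in% key)
    }
  }
})
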