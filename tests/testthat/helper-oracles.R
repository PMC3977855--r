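# Brute-force oracles, written independently of the package internals:
# cubic all-pairs distances, explicit shortest-path enumeration, union-find
# components, dense eigendecomposition. Deliberately slow and simple.

# random graph for oracle comparisons (direct Bernoulli over pairs)
rg <- function(n, p, seed) {
  set.seed(seed)
  pairs <- t(utils::combn(n, 2))
  hit <- stats::runif(nrow(pairs)) < p
  labs <- sprintf("n%02d", seq_len(n))
  graph_from_edges(cbind(labs[pairs[hit, 1]], labs[pairs[hit, 2]]),
                   nodes = labs)
}

rg_connected <- function(n, p, seed) {
  for (s in seed + 0:200) {
    g <- rg(n, p, s)
    if (length(unique(o_components(g))) == 1L) return(g)
  }
  stop("no connected sample found")
}

o_adj_matrix <- function(g) {
  n <- length(g$nodes)
  A <- matrix(0, n, n, dimnames = list(g$nodes, g$nodes))
  if (nrow(g$edges)) {
    for (e in seq_len(nrow(g$edges))) {
      i <- match(g$edges[e, 1], g$nodes); j <- match(g$edges[e, 2], g$nodes)
      A[i, j] <- A[j, i] <- 1
    }
  }
  A
}

# Floyd-Warshall; Inf = unreachable
o_floyd <- function(g) {
  A <- o_adj_matrix(g)
  n <- nrow(A)
  D <- ifelse(A > 0, 1, Inf)
  diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  }
  D
}

# enumerate all shortest s-t paths by DFS descending the distance-to-t field;
# returns sigma counts and per-interior-node pass-through counts
o_enumerate <- function(g) {
  D <- o_floyd(g)
  A <- o_adj_matrix(g)
  n <- nrow(A)
  sigma <- matrix(0, n, n, dimnames = dimnames(A))
  diag(sigma) <- 1
  through <- array(0, c(n, n, n),
                   dimnames = list(g$nodes, g$nodes, g$nodes))
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t || !is.finite(D[s, t])) next
    paths <- list()
    walk <- function(v, acc) {
      if (v == t) { paths[[length(paths) + 1L]] <<- acc; return(invisible()) }
      for (w in which(A[v, ] > 0)) {
        if (is.finite(D[w, t]) && D[w, t] == D[v, t] - 1) walk(w, c(acc, w))
      }
    }
    walk(s, s)
    sigma[s, t] <- length(paths)
    for (p in paths) {
      interior <- setdiff(p, c(s, t))
      for (v in interior) through[s, t, v] <- through[s, t, v] + 1
    }
  }
  list(sigma = sigma, through = through, dist = D)
}

# betweenness directly from enumerated paths (unordered pairs, endpoints excluded)
o_betweenness <- function(g) {
  en <- o_enumerate(g)
  n <- length(g$nodes)
  cb <- stats::setNames(numeric(n), g$nodes)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    if (en$sigma[s, t] == 0) next
    cb <- cb + en$through[s, t, ] / en$sigma[s, t]
  }
  cb
}

# union-find component membership
o_components <- function(g) {
  n <- length(g$nodes)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  if (nrow(g$edges)) {
    for (e in seq_len(nrow(g$edges))) {
      a <- find(match(g$edges[e, 1], g$nodes))
      b <- find(match(g$edges[e, 2], g$nodes))
      if (a != b) parent[a] <- b
    }
  }
  stats::setNames(vapply(seq_len(n), find, integer(1)), g$nodes)
}

o_lcc_nodes <- function(g) {
  comp <- o_components(g)
  sizes <- table(comp)
  best <- names(sizes)[sizes == max(sizes)]
  if (length(best) > 1L) {
    firsts <- vapply(best, function(k) min(sort(names(comp)[comp == as.integer(k)])),
                     character(1))
    best <- best[order(firsts)][1L]
  }
  sort(names(comp)[comp == as.integer(best)])
}

o_closeness <- function(g) {
  keep <- o_lcc_nodes(g)
  D <- o_floyd(g)[keep, keep, drop = FALSE]
  stats::setNames(1 / rowSums(D), keep)
}

o_eccentricity <- function(g) {
  keep <- o_lcc_nodes(g)
  D <- o_floyd(g)[keep, keep, drop = FALSE]
  stats::setNames(apply(D, 1, max), keep)
}

o_degree <- function(g) {
  A <- o_adj_matrix(g)
  rowSums(A) / (nrow(A) - 1)
}

# dense symmetric eigendecomposition; dominant eigenvector, nonnegative, unit norm
o_eigenvector <- function(g) {
  A <- o_adj_matrix(g)
  es <- eigen(A, symmetric = TRUE)
  v <- es$vectors[, which.max(es$values)]
  v <- abs(v) / sqrt(sum(v^2))
  stats::setNames(v, g$nodes)
}
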