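#' Breadth-first hop distances from one node
#'
#' @param g a `netgraph`
#' @param source node label, must be in `g`
#' @param adj optional precomputed [graph_adjacency()] list (perf hook for
#'   all-pairs loops)
#' @return named integer vector of hop counts for every *reachable* node
#'   (including `source` at 0); unreachable nodes are absent. The source label
#'   is attached as attribute `source`.
#' @export
bfs_distances <- function(g, source, adj = NULL) {
  s <- match(as.character(source), g$nodes)
  if (is.na(s)) stop("unknown source node: ", source)
  if (is.null(adj)) adj <- graph_adjacency(g)
  d <- bfs_dist_idx(adj, s)
  reach <- which(d >= 0L)
  out <- d[reach]
  names(out) <- g$nodes[reach]
  attr(out, "source") <- g$nodes[s]
  out
}

# index-level BFS: returns integer vector, -1 = unreachable
bfs_dist_idx <- function(adj, s) {
  n <- length(adj)
  d <- rep.int(-1L, n)
  d[s] <- 0L
  queue <- integer(n)
  queue[1L] <- s
  head <- 1L; tail <- 1L
  while (head <= tail) {
    v <- queue[head]; head <- head + 1L
    for (w in adj[[v]]) {
      if (d[w] < 0L) {
        d[w] <- d[v] + 1L
        tail <- tail + 1L
        queue[tail] <- w
      }
    }
  }
  d
}

# all-pairs hop distances; -1 = unreachable (integer matrix, labelled)
all_pairs_distances <- function(g) {
  adj <- graph_adjacency(g)
  n <- length(adj)
  D <- matrix(-1L, n, n, dimnames = list(g$nodes, g$nodes))
  for (s in seq_len(n)) D[s, ] <- bfs_dist_idx(adj, s)
  D
}

#' Count geodesics between all node pairs
#'
#' `sigma[s, t]` counts distinct shortest s-t paths (`sigma[s, s] = 1` by
#' convention; 0 when t is unreachable). With `through = TRUE` a dense
#' `n x n x n` array is also returned where `through[s, t, v]` counts the
#' shortest s-t paths passing through *interior* node v; it follows the
#' composition identity sigma_st(v) = sigma_sv * sigma_vt when v lies on a
#' geodesic, which agrees with explicit path enumeration. The cube is meant
#' for small graphs (oracle work, planted examples); it is refused above
#' `max_through_nodes`.
#'
#' @param g a non-empty `netgraph`
#' @param through also compute the pass-through counts
#' @param max_through_nodes guard on the O(n^3) array
#' @return list with `sigma` (matrix) and, if requested, `through` (3-d array),
#'   plus `dist` (hop-distance matrix), class `geodesic_counts`
#' @export
count_geodesics <- function(g, through = TRUE, max_through_nodes = 150L) {
  n <- n_nodes(g)
  if (n == 0L) stop("empty graph")
  adj <- graph_adjacency(g)
  D <- matrix(-1L, n, n)
  S <- matrix(0, n, n)
  for (s in seq_len(n)) {
    d <- bfs_dist_idx(adj, s)
    sig <- numeric(n); sig[s] <- 1
    ord <- order(replace(d, d < 0L, NA), na.last = NA)  # reachable, by distance
    for (v in ord) {
      if (v == s) next
      for (u in adj[[v]]) if (d[u] == d[v] - 1L) sig[v] <- sig[v] + sig[u]
    }
    D[s, ] <- d
    S[s, ] <- sig
  }
  dimnames(D) <- dimnames(S) <- list(g$nodes, g$nodes)
  out <- list(sigma = S, dist = D)
  if (through) {
    if (n > max_through_nodes) {
      stop("pass-through counts need O(n^3) memory; refusing for n = ", n)
    }
    TH <- array(0, c(n, n, n), dimnames = list(g$nodes, g$nodes, g$nodes))
    for (s in seq_len(n)) for (t in seq_len(n)) {
      if (s == t || D[s, t] < 0L) next
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        if (D[s, v] >= 0L && D[v, t] >= 0L && D[s, v] + D[v, t] == D[s, t]) {
          TH[s, t, v] <- S[s, v] * S[v, t]
        }
      }
    }
    out$through <- TH
  }
  structure(out, class = "geodesic_counts")
}

# connected component membership: integer vector, components numbered from 1
component_membership <- function(g) {
  adj <- graph_adjacency(g)
  n <- length(adj)
  comp <- integer(n)
  k <- 0L
  for (s in seq_len(n)) {
    if (comp[s] == 0L) {
      k <- k + 1L
      d <- bfs_dist_idx(adj, s)
      comp[d >= 0L] <- k
    }
  }
  names(comp) <- g$nodes
  comp
}

#' Largest connected component
#'
#' Ties on component size are broken by the smallest lexicographic node label
#' occurring in the component, so the choice is deterministic.
#'
#' @param g a non-empty `netgraph`
#' @return the induced `netgraph` on the winning component
#' @export
largest_connected_component <- function(g) {
  if (n_nodes(g) == 0L) stop("empty graph")
  comp <- component_membership(g)
  sizes <- table(comp)
  best <- as.integer(names(sizes)[sizes == max(sizes)])
  if (length(best) > 1L) {
    firsts <- vapply(best, function(k) min(sort(g$nodes[comp == k])), character(1))
    best <- best[order(firsts)][1L]
  }
  induced_subgraph(g, g$nodes[comp == best])
}
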