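#' Undirected simple graph over labelled nodes
#'
#' The package's graph container is deliberately minimal: an ordered set of
#' character node labels plus a canonicalised two-column edge matrix. Node
#' identity is the string label throughout (named animals and numbered club
#' members share one key type). Edges are unordered pairs; self-loops and
#' duplicates are never stored.
#'
#' @param edges two-column character matrix (or coercible data.frame) of edge
#'   endpoints; duplicates and reversed duplicates are collapsed, self-loops
#'   dropped.
#' @param nodes optional character vector giving the full ordered node set
#'   (isolated nodes included). Endpoints not listed are appended in order of
#'   first appearance.
#' @param warn logical; warn when self-loops or duplicate edges are discarded.
#' @return an object of class `netgraph` with elements `nodes` (character)
#'   and `edges` (two-column character matrix, lexicographically canonical).
#' @examples
#' g <- graph_from_edges(rbind(c("a", "b"), c("b", "c")))
#' n_nodes(g); n_edges(g)
#' @export
graph_from_edges <- function(edges, nodes = NULL, warn = FALSE) {
  if (is.null(edges) || (is.matrix(edges) && nrow(edges) == 0L) ||
      (is.data.frame(edges) && nrow(edges) == 0L) || length(edges) == 0L) {
    em <- matrix(character(0), ncol = 2L)
  } else {
    em <- as.matrix(edges)
    if (ncol(em) != 2L) stop("`edges` must have exactly two columns")
    storage.mode(em) <- "character"
  }
  loops <- em[, 1L] == em[, 2L]
  if (any(loops)) {
    if (warn) warning(sum(loops), " self-loop(s) dropped")
    em <- em[!loops, , drop = FALSE]
  }
  if (nrow(em) > 0L) {
    canon <- cbind(pmin(em[, 1L], em[, 2L]), pmax(em[, 1L], em[, 2L]))
    dup <- duplicated(paste(canon[, 1L], canon[, 2L], sep = "\r"))
    if (any(dup) && warn) {
      warning(sum(dup), " duplicate/reciprocal edge(s) collapsed")
    }
    em <- canon[!dup, , drop = FALSE]
    em <- em[order(em[, 1L], em[, 2L], method = "radix"), , drop = FALSE]
  }
  seen <- unique(as.vector(t(em)))
  nodes <- if (is.null(nodes)) seen else {
    nodes <- as.character(nodes)
    if (anyDuplicated(nodes)) stop("duplicate node labels in `nodes`")
    c(nodes, setdiff(seen, nodes))
  }
  new_netgraph(nodes, em)
}

# internal constructor: trusts canonical input
new_netgraph <- function(nodes, edges) {
  structure(list(nodes = nodes, edges = edges), class = "netgraph")
}

#' @export
print.netgraph <- function(x, ...) {
  cat(sprintf("<netgraph> %d nodes, %d edges\n", n_nodes(x), n_edges(x)))
  invisible(x)
}

#' Node and edge counts
#' @param g a `netgraph`
#' @return integer scalar
#' @export
n_nodes <- function(g) length(g$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(g) nrow(g$edges)

#' Adjacency list of integer node indices
#'
#' @param g a `netgraph`
#' @return list, one integer vector of neighbour indices per node (indices
#'   into `g$nodes`)
#' @export
graph_adjacency <- function(g) {
  n <- n_nodes(g)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer(0)
  if (n_edges(g) > 0L) {
    a <- match(g$edges[, 1L], g$nodes)
    b <- match(g$edges[, 2L], g$nodes)
    adj <- split(c(b, a), factor(c(a, b), levels = seq_len(n)))
    adj <- lapply(adj, function(v) as.integer(sort(v)))
  }
  names(adj) <- g$nodes
  adj
}

# dense 0/1 adjacency matrix (small graphs only)
adjacency_matrix <- function(g) {
  n <- n_nodes(g)
  A <- matrix(0, n, n, dimnames = list(g$nodes, g$nodes))
  if (n_edges(g) > 0L) {
    i <- match(g$edges[, 1L], g$nodes)
    j <- match(g$edges[, 2L], g$nodes)
    A[cbind(i, j)] <- 1
    A[cbind(j, i)] <- 1
  }
  A
}

#' Integer degree of every node
#' @param g a `netgraph`
#' @return named integer vector
#' @export
node_degrees <- function(g) {
  n <- n_nodes(g)
  d <- integer(n)
  if (n_edges(g) > 0L) {
    idx <- c(match(g$edges[, 1L], g$nodes), match(g$edges[, 2L], g$nodes))
    d <- as.integer(tabulate(idx, nbins = n))
  }
  names(d) <- g$nodes
  d
}

#' Induced subgraph on a node subset
#' @param g a `netgraph`
#' @param keep character vector of node labels to retain
#' @return a `netgraph`
#' @export
induced_subgraph <- function(g, keep) {
  keep <- as.character(keep)
  if (!all(keep %in% g$nodes)) stop("`keep` contains labels not in the graph")
  sel <- g$edges[, 1L] %in% keep & g$edges[, 2L] %in% keep
  new_netgraph(g$nodes[g$nodes %in% keep], g$edges[sel, , drop = FALSE])
}
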