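#' Run code with a temporarily seeded RNG
#'
#' Seeds the generator, evaluates, and restores the caller's RNG state, so
#' generators are reproducible without clobbering the session.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

#' Graph with machine-readable ground-truth influential nodes
#'
#' Wraps a graph together with the node set documented (or constructed) to be
#' influential, so recovery by a centrality measure can be scored.
#'
#' @param graph a `netgraph`
#' @param influential character vector of node labels (may be empty for
#'   datasets without documented key nodes)
#' @param construction free-text provenance: generator name + parameters, or
#'   dataset origin
#' @return an `annotated_graph`
#' @export
annotated_graph <- function(graph, influential, construction = "") {
  influential <- as.character(influential)
  if (!all(influential %in% graph$nodes)) {
    stop("influential nodes must be members of the graph")
  }
  structure(list(graph = graph, influential = influential,
                 construction = construction),
            class = "annotated_graph")
}

#' @export
print.annotated_graph <- function(x, ...) {
  cat(sprintf("<annotated_graph> %d nodes, %d edges; influential: {%s}\n  %s\n",
              n_nodes(x$graph), n_edges(x$graph),
              paste(x$influential, collapse = ", "), x$construction))
  invisible(x)
}

#' Erdos-Renyi G(n, p) random graph
#'
#' Each of the C(n, 2) unordered node pairs is included independently with
#' probability p. Pairs are visited in a fixed deterministic order
#' ((1,2), (1,3), ..., (n-1,n)), so a given seed yields the same edge set on
#' any platform. Node labels are `"1" .. "n"`; isolated nodes are kept.
#'
#' The study's baseline was a single unseeded draw at n = 50, p = 0.1 (which
#' happened to have 135 edges); this generator reproduces the *distribution*
#' Binomial(C(n,2), p), not that one realisation.
#'
#' @param n node count (>= 1)
#' @param p edge probability in \[0, 1\]
#' @param seed integer RNG seed (`NULL` = use current RNG state)
#' @return a `netgraph`
#' @examples
#' n_edges(erdos_renyi(50, 0.1, seed = 1))
#' @export
erdos_renyi <- function(n, p, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    stop("`n` must be a positive integer")
  }
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    stop("`p` must be a probability in [0, 1]")
  }
  n <- as.integer(n)
  labels <- as.character(seq_len(n))
  npairs <- n * (n - 1L) / 2
  hit <- with_seed(seed, stats::runif(npairs) < p)
  if (npairs > 0L && any(hit)) {
    i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
    j <- sequence((n - 1L):1L) + i
    em <- cbind(labels[i[hit]], labels[j[hit]])
  } else {
    em <- matrix(character(0), ncol = 2L)
  }
  graph_from_edges(em, nodes = labels)
}

#' Planted-hub graph: a star with a sparse random ring among the spokes
#'
#' A hub adjacent to every spoke, plus each consecutive spoke pair (around a
#' ring) independently kept with probability `rewire`. The hub is the ground-
#' truth influential node; for `rewire < 1` a spoke's degree is at most 3, so
#' the hub has strictly maximal degree whenever `n_spokes > 3`.
#'
#' @param n_spokes number of spokes (>= 3)
#' @param rewire probability of each ring edge
#' @param seed integer RNG seed
#' @return an `annotated_graph` with `influential = "hub"`
#' @export
planted_hub <- function(n_spokes, rewire = 0.1, seed = NULL) {
  if (n_spokes < 3L) stop("`n_spokes` must be >= 3")
  if (rewire < 0 || rewire > 1) stop("`rewire` must be in [0, 1]")
  n_spokes <- as.integer(n_spokes)
  spokes <- sprintf("s%02d", seq_len(n_spokes))
  star <- cbind("hub", spokes)
  ring <- cbind(spokes, spokes[c(2:n_spokes, 1L)])
  keep <- with_seed(seed, stats::runif(n_spokes) < rewire)
  g <- graph_from_edges(rbind(star, ring[keep, , drop = FALSE]),
                        nodes = c("hub", spokes))
  annotated_graph(g, "hub",
                  sprintf("planted_hub(n_spokes=%d, rewire=%g, seed=%s)",
                          n_spokes, rewire, format(seed)))
}

#' Planted-bridge graph: two cliques joined through a single broker
#'
#' Two disjoint cliques of size `clique_size` connected only through a broker
#' node adjacent to one node of each clique. Every cross-clique geodesic runs
#' through the broker, so its betweenness is clique_size^2 x (fraction via
#' broker) while its degree stays 2; removing it disconnects the graph.
#'
#' @param clique_size size of each clique (>= 3)
#' @param seed accepted for API symmetry; the construction is deterministic
#' @return an `annotated_graph` with `influential = "broker"`
#' @export
planted_bridge <- function(clique_size, seed = NULL) {
  if (clique_size < 3L) stop("`clique_size` must be >= 3")
  k <- as.integer(clique_size)
  a <- sprintf("a%02d", seq_len(k))
  b <- sprintf("b%02d", seq_len(k))
  clique <- function(v) t(utils::combn(v, 2L))
  em <- rbind(clique(a), clique(b), c("broker", a[1L]), c("broker", b[1L]))
  g <- graph_from_edges(em, nodes = c(a, "broker", b))
  annotated_graph(g, "broker",
                  sprintf("planted_bridge(clique_size=%d)", k))
}

#' Bundled benchmark networks with documented key nodes
#'
#' Loads one of the vendored classic networks from the package's plain-text
#' edge lists and attaches the ground-truth influential nodes documented in
#' the originating field studies:
#' * `karate`: Zachary's karate club (34 nodes / 78 edges); influential =
#'   nodes `1` (instructor) and `34` (president), the two information sources.
#' * `dolphins`: Doubtful Sound bottlenose dolphins (62 nodes / 159 edges);
#'   influential = `Grin` and `SN100`, the individuals singled out by the
#'   published analyses.
#' * `celegans`: C. elegans neural network (297 nodes; 2359 directed synaptic
#'   connection records collapsing to 2148 undirected simple edges). No node
#'   identities are documented, so the influential set is empty and a warning
#'   is raised.
#'
#' @param name one of `"karate"`, `"dolphins"`, `"celegans"`
#' @return an `annotated_graph`
#' @export
bundled_fixture <- function(name) {
  valid <- c("karate", "dolphins", "celegans")
  if (!is.character(name) || length(name) != 1L || !(name %in% valid)) {
    stop("unknown fixture '", paste(name, collapse = ","),
         "'; valid names: ", paste(valid, collapse = ", "))
  }
  path <- system.file("extdata", paste0(name, ".edgelist"), package = "keynodes",
                      mustWork = TRUE)
  lines <- readLines(path, warn = FALSE)
  records <- sum(!grepl("^\\s*(#|$)", lines))
  g <- suppressWarnings(read_edge_list(lines))
  influential <- switch(name,
    karate = c("1", "34"),
    dolphins = c("Grin", "SN100"),
    celegans = character(0)
  )
  if (name == "celegans") {
    warning("celegans: no documented node identities; ground-truth set is empty")
  }
  annotated_graph(g, influential,
                  sprintf("bundled_fixture('%s'): %d edge records in %s",
                          name, records, basename(path)))
}
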