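#' Centrality score vectors
#'
#' All five measures return a `centrality_vector`: a named numeric `scores`
#' vector, the measure name, a human-readable `normalization` descriptor, and
#' (for the distance-based measures on disconnected input) the node labels of
#' the largest connected component the scores were restricted to.
#'
#' Conventions, chosen once and exposed as flags:
#' * degree: deg(v)/(n-1) (Freeman), raw degree via `normalized = FALSE`;
#' * betweenness: sum over unordered pairs of sigma_st(v)/sigma_st, endpoints
#'   excluded, unnormalised by default (`normalized = TRUE` divides by
#'   C(n-1, 2));
#' * closeness: raw inverse farness 1/sum_t d(v,t) (Sabidussi); the
#'   `"freeman"` variant rescales by (n_c - 1);
#' * eccentricity: the largest geodesic distance itself (reports invert it
#'   where "small = central" is wanted);
#' * eigenvector: dominant adjacency eigenvector, nonnegative, unit Euclidean
#'   norm, via power iteration.
#'
#' @name centrality_vector
#' @keywords internal
NULL

new_centrality_vector <- function(measure, scores, normalization, component = NULL) {
  structure(list(measure = measure, scores = scores,
                 normalization = normalization, component = component),
            class = "centrality_vector")
}

#' @export
print.centrality_vector <- function(x, ...) {
  cat(sprintf("<centrality_vector> %s (%s), %d nodes\n",
              x$measure, x$normalization, length(x$scores)))
  if (!is.null(x$component)) {
    cat(sprintf("  restricted to largest component (%d nodes)\n", length(x$component)))
  }
  invisible(x)
}

#' Degree centrality
#'
#' @param g a `netgraph` with at least 2 nodes (when normalising)
#' @param normalized divide by (n - 1); `FALSE` returns raw degree
#' @return a `centrality_vector`
#' @examples
#' degree_centrality(graph_from_edges(rbind(c("a","b"), c("b","c"))))
#' @export
degree_centrality <- function(g, normalized = TRUE) {
  n <- n_nodes(g)
  d <- as.numeric(node_degrees(g))
  names(d) <- g$nodes
  if (normalized) {
    if (n < 2L) stop("degree normalisation needs at least 2 nodes")
    d <- d / (n - 1)
  }
  new_centrality_vector("degree", d, if (normalized) "deg/(n-1)" else "raw degree")
}

#' Betweenness centrality (Brandes accumulation)
#'
#' Exact shortest-path betweenness over unordered pairs, endpoints excluded.
#'
#' @param g a `netgraph`
#' @param normalized divide by C(n-1, 2)
#' @return a `centrality_vector`
#' @export
betweenness_centrality <- function(g, normalized = FALSE) {
  adj <- graph_adjacency(g)
  n <- length(adj)
  cb <- numeric(n)
  if (n > 0L) {
    for (s in seq_len(n)) {
      sigma <- numeric(n); sigma[s] <- 1
      dist <- rep.int(-1L, n); dist[s] <- 0L
      preds <- vector("list", n)
      stack <- integer(n); top <- 0L
      queue <- integer(n); queue[1L] <- s; head <- 1L; tail <- 1L
      while (head <= tail) {
        v <- queue[head]; head <- head + 1L
        top <- top + 1L; stack[top] <- v
        for (w in adj[[v]]) {
          if (dist[w] < 0L) {
            dist[w] <- dist[v] + 1L
            tail <- tail + 1L; queue[tail] <- w
          }
          if (dist[w] == dist[v] + 1L) {
            sigma[w] <- sigma[w] + sigma[v]
            preds[[w]] <- c(preds[[w]], v)
          }
        }
      }
      delta <- numeric(n)
      while (top > 0L) {
        w <- stack[top]; top <- top - 1L
        for (v in preds[[w]]) {
          delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
        }
        if (w != s) cb[w] <- cb[w] + delta[w]
      }
    }
    cb <- cb / 2  # ordered -> unordered pairs
  }
  if (normalized && n > 2L) cb <- cb / choose(n - 1, 2)
  names(cb) <- g$nodes
  new_centrality_vector(
    "betweenness", cb,
    if (normalized) "pairs / C(n-1,2)" else "unordered pairs, unnormalised"
  )
}

# distance-based measures share the component restriction
component_for_distances <- function(g) {
  lcc <- largest_connected_component(g)
  restricted <- n_nodes(lcc) < n_nodes(g)
  if (restricted) {
    warning("graph is disconnected; distance-based centrality restricted to ",
            "the largest connected component (", n_nodes(lcc), " of ",
            n_nodes(g), " nodes)")
  }
  list(lcc = lcc, component = if (restricted) lcc$nodes else NULL)
}

#' Closeness centrality (inverse farness)
#'
#' On disconnected input the scores are computed on the largest connected
#' component only, with a warning.
#'
#' @param g a `netgraph` whose largest component has at least 2 nodes
#' @param variant `"raw"` = 1/farness; `"freeman"` = (n_c - 1)/farness
#' @return a `centrality_vector`
#' @export
closeness_centrality <- function(g, variant = c("raw", "freeman")) {
  variant <- match.arg(variant)
  cf <- component_for_distances(g)
  lcc <- cf$lcc
  nc <- n_nodes(lcc)
  if (nc < 2L) stop("closeness undefined on a single-node component")
  adj <- graph_adjacency(lcc)
  farness <- vapply(seq_len(nc), function(s) sum(bfs_dist_idx(adj, s)), numeric(1))
  sc <- if (variant == "raw") 1 / farness else (nc - 1) / farness
  names(sc) <- lcc$nodes
  new_centrality_vector(
    "closeness", sc,
    if (variant == "raw") "1/farness" else "(n-1)/farness",
    component = cf$component
  )
}

#' Eccentricity centrality
#'
#' The largest geodesic distance from each node to any other node of the
#' largest connected component. The minimum over nodes is the radius, the
#' maximum the diameter. Note the orientation: *small* eccentricity means
#' *central*; report layers invert it when a "high = central" scale is needed.
#'
#' @param g a `netgraph` whose largest component has at least 2 nodes
#' @return a `centrality_vector` with positive integer scores
#' @export
eccentricity_centrality <- function(g) {
  cf <- component_for_distances(g)
  lcc <- cf$lcc
  nc <- n_nodes(lcc)
  if (nc < 2L) stop("eccentricity undefined on a single-node component")
  adj <- graph_adjacency(lcc)
  ecc <- vapply(seq_len(nc), function(s) max(bfs_dist_idx(adj, s)), integer(1))
  ecc <- as.numeric(ecc)
  names(ecc) <- lcc$nodes
  new_centrality_vector("eccentricity", ecc, "max geodesic distance (hops)",
                        component = cf$component)
}

#' Eigenvector centrality by power iteration
#'
#' Iterates the adjacency operator from the uniform positive start vector with
#' Euclidean renormalisation, stopping when the max-norm difference of
#' successive iterates falls below `tol`. On bipartite graphs the +/- lambda
#' eigenvalue pair can make the iteration oscillate; when non-convergence is
#' detected the iteration is re-run on the shifted operator A + I (which has
#' the same dominant eigenvector) and the shift is recorded.
#'
#' @param g a `netgraph` with at least one edge
#' @param tol max-norm convergence tolerance for successive iterates
#' @param max_iter iteration cap (per attempt)
#' @return an `eigen_result`: `eigenvalue` (Rayleigh quotient on A), `vector`
#'   (a nonnegative unit-norm `centrality_vector`), `iterations`, `residual`
#'   (max-norm of A v - lambda v), and `shift` (0 or 1)
#' @export
eigenvector_centrality <- function(g, tol = 1e-10, max_iter = 1000L) {
  if (n_edges(g) == 0L) stop("eigenvector centrality needs at least one edge")
  A <- adjacency_matrix(g)
  n <- nrow(A)

  run <- function(M) {
    v <- rep(1 / sqrt(n), n)
    for (it in seq_len(max_iter)) {
      w <- as.vector(M %*% v)
      nrm <- sqrt(sum(w * w))
      if (nrm == 0) stop("power iteration annihilated the start vector")
      w <- w / nrm
      if (max(abs(w - v)) < tol) return(list(v = w, iterations = it, converged = TRUE))
      v <- w
    }
    list(v = v, iterations = max_iter, converged = FALSE)
  }

  res <- run(A)
  shift <- 0
  if (!res$converged) {
    res <- run(A + diag(n))
    shift <- 1
    if (!res$converged) {
      lam <- as.numeric(crossprod(res$v, A %*% res$v))
      resid <- max(abs(as.vector(A %*% res$v) - lam * res$v))
      stop(sprintf(paste0("eigenvector power iteration failed to converge in %d ",
                          "iterations even with damping shift (residual %.3e)"),
                   max_iter, resid))
    }
  }
  v <- abs(res$v)  # nonneg up to sign; start is positive so this is a no-op
  v <- v / sqrt(sum(v * v))
  lambda <- as.numeric(crossprod(v, A %*% v))
  residual <- max(abs(as.vector(A %*% v) - lambda * v))
  names(v) <- g$nodes
  structure(
    list(eigenvalue = lambda,
         vector = new_centrality_vector("eigenvector", v, "unit Euclidean norm"),
         iterations = res$iterations, residual = residual, shift = shift),
    class = "eigen_result"
  )
}

#' @export
print.eigen_result <- function(x, ...) {
  cat(sprintf("<eigen_result> lambda = %.6g, %d iterations, residual %.2e%s\n",
              x$eigenvalue, x$iterations, x$residual,
              if (x$shift > 0) sprintf(", damping shift A + %gI", x$shift) else ""))
  invisible(x)
}

#' Compute all five centrality vectors on one graph
#'
#' @param g a `netgraph` with at least 2 nodes
#' @param id identifier recorded in the profile
#' @param degree_normalized,betweenness_normalized,closeness_variant
#'   convention flags, see the individual measures
#' @param tol,max_iter forwarded to [eigenvector_centrality()]
#' @return a `centrality_profile`: `id`, `vectors` (named list of the five
#'   `centrality_vector`s), `component` (labels, when closeness/eccentricity
#'   were restricted), `eigen` (the full `eigen_result`), `n_nodes`
#' @export
compute_profile <- function(g, id = "graph",
                            degree_normalized = TRUE,
                            betweenness_normalized = FALSE,
                            closeness_variant = "raw",
                            tol = 1e-10, max_iter = 1000L) {
  if (n_nodes(g) < 2L) stop("profiles need at least 2 nodes")
  deg <- degree_centrality(g, normalized = degree_normalized)
  btw <- betweenness_centrality(g, normalized = betweenness_normalized)
  clo <- closeness_centrality(g, variant = closeness_variant)
  ecc <- eccentricity_centrality(g)
  eig <- eigenvector_centrality(g, tol = tol, max_iter = max_iter)
  structure(
    list(id = id,
         vectors = list(degree = deg, betweenness = btw, closeness = clo,
                        eccentricity = ecc, eigenvector = eig$vector),
         component = clo$component,
         eigen = eig,
         n_nodes = n_nodes(g)),
    class = "centrality_profile"
  )
}

#' @export
print.centrality_profile <- function(x, ...) {
  cat(sprintf("<centrality_profile> '%s': 5 measures on %d nodes\n", x$id, x$n_nodes))
  if (!is.null(x$component)) {
    cat(sprintf("  closeness/eccentricity restricted to %d-node component\n",
                length(x$component)))
  }
  invisible(x)
}

#' Names of the five measures, in canonical order
#' @return character vector
#' @export
centrality_measures <- function() {
  c("degree", "betweenness", "closeness", "eccentricity", "eigenvector")
}
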