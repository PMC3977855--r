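# round to 12 significant digits before any tie comparison, so equal-by-maths
# scores that differ only in the last floating-point bits count as tied
round12 <- function(x) signif(x, 12)

#' Extreme (most/least central) node sets of one measure
#'
#' Scores are rounded to 12 significant digits, then nodes within `tol` of the
#' maximum (minimum) form the argmax (argmin) set. Because printed "number of
#' nodes at the extreme value" counts in the literature sometimes derive from
#' histogram binning rather than exact ties, a 10-bin equal-width histogram
#' fallback count is reported alongside the exact tie counts.
#'
#' @param vec a `centrality_vector` (or named numeric vector)
#' @param tol absolute tie tolerance after rounding
#' @return an `extreme_summary`: measure, max/min values, argmax/argmin node
#'   sets, exact tie counts `n_max`/`n_min`, histogram fallback counts
#'   `hist_n_max`/`hist_n_min`, and a `constant` flag
#' @export
extreme_node_sets <- function(vec, tol = 1e-9) {
  measure <- if (inherits(vec, "centrality_vector")) vec$measure else "scores"
  s <- if (inherits(vec, "centrality_vector")) vec$scores else vec
  if (length(s) == 0L) stop("empty centrality vector")
  s <- round12(s)
  mx <- max(s); mn <- min(s)
  constant <- (mx - mn) <= tol
  argmax <- sort(names(s)[s >= mx - tol])
  argmin <- sort(names(s)[s <= mn + tol])
  w <- (mx - mn) / 10
  hist_n_min <- if (constant) length(s) else sum(s < mn + w)
  hist_n_max <- if (constant) length(s) else sum(s > mx - w)
  structure(
    list(measure = measure, max_value = mx, argmax_nodes = argmax,
         n_max = length(argmax), min_value = mn, argmin_nodes = argmin,
         n_min = length(argmin), hist_n_max = hist_n_max,
         hist_n_min = hist_n_min, constant = constant),
    class = "extreme_summary"
  )
}

#' @export
print.extreme_summary <- function(x, ...) {
  cat(sprintf("<extreme_summary> %s%s\n  max %.6g at %d node(s); min %.6g at %d node(s)\n",
              x$measure, if (x$constant) " [constant]" else "",
              x$max_value, x$n_max, x$min_value, x$n_min))
  invisible(x)
}

# shared node universe across the five vectors; warn when the distance-based
# measures were component-restricted
profile_universe <- function(profile) {
  universes <- lapply(profile$vectors, function(v) names(v$scores))
  shared <- Reduce(intersect, universes)
  if (length(shared) < max(lengths(universes))) {
    warning("measures computed on different node sets; using the ",
            length(shared), "-node intersection")
  }
  shared
}

# score matrix on the shared universe with eccentricity sign-flipped so that
# larger = more central for every column
profile_score_matrix <- function(profile, flip_eccentricity = TRUE) {
  shared <- profile_universe(profile)
  if (length(shared) < 3L) stop("fewer than 3 shared nodes across measures")
  M <- vapply(centrality_measures(),
              function(m) unname(profile$vectors[[m]]$scores[shared]),
              numeric(length(shared)))
  rownames(M) <- shared
  if (flip_eccentricity) M[, "eccentricity"] <- -M[, "eccentricity"]
  M
}

#' Pairwise rank correlation of the five measures
#'
#' Tie-aware rank correlation (Kendall tau-b by default; tie-heavy vectors
#' like eccentricity demand it) between every pair of centrality vectors on
#' their shared node universe. Eccentricity is sign-flipped before ranking so
#' that "more central" is larger for all measures; the flip is recorded.
#'
#' @param profile a `centrality_profile`
#' @param method `"kendall"` (tau-b) or `"spearman"`
#' @return a `correlation_matrix`: `method`, 5 x 5 `entries`, `flipped`,
#'   `n_nodes`
#' @export
rank_correlation <- function(profile, method = c("kendall", "spearman")) {
  method <- match.arg(method)
  M <- profile_score_matrix(profile, flip_eccentricity = TRUE)
  entries <- suppressWarnings(stats::cor(M, method = method))
  diag(entries) <- 1
  entries <- (entries + t(entries)) / 2  # enforce exact symmetry
  structure(
    list(method = method, entries = entries, flipped = "eccentricity",
         n_nodes = nrow(M)),
    class = "correlation_matrix"
  )
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("<correlation_matrix> %s on %d nodes (eccentricity sign-flipped)\n",
              x$method, x$n_nodes))
  print(round(x$entries, 3))
  invisible(x)
}

# deterministic "most central first" ranking of node labels for one measure:
# score descending (eccentricity inverted), ties by lexicographic label
ranked_labels <- function(profile, measure) {
  v <- profile$vectors[[measure]]
  s <- round12(v$scores)
  if (measure == "eccentricity") s <- -s
  names(s)[order(-s, names(s), method = "radix")]
}

# competition rank (ties share the best rank) of each node for one measure
competition_ranks <- function(profile, measure) {
  v <- profile$vectors[[measure]]
  s <- round12(v$scores)
  if (measure == "eccentricity") s <- -s
  r <- rank(-s, ties.method = "min")
  names(r) <- names(s)
  r
}

#' Top-k concordance between measures
#'
#' For each measure the k most central nodes are taken (eccentricity
#' inverted; ties at the k-boundary broken by lexicographic node label and
#' recorded), and every pair of measures is scored by |top-k intersection|/k.
#'
#' @param profile a `centrality_profile`
#' @param k cut-off, 1 <= k <= n
#' @return a `topk_overlap`: `k`, 5 x 5 `entries`, `top` (list of top-k label
#'   vectors), `boundary_ties` (logical per measure)
#' @export
top_k_overlap <- function(profile, k = 5L) {
  n_min <- min(lengths(lapply(profile$vectors, function(v) v$scores)))
  if (k < 1L || k > n_min) stop("`k` must be between 1 and ", n_min)
  measures <- centrality_measures()
  top <- list(); ties <- logical(length(measures)); names(ties) <- measures
  for (m in measures) {
    lab <- ranked_labels(profile, m)
    s <- round12(profile$vectors[[m]]$scores)[lab]
    top[[m]] <- lab[seq_len(k)]
    ties[m] <- length(lab) > k && isTRUE(abs(s[k] - s[k + 1L]) <= 1e-9)
  }
  E <- matrix(NA_real_, 5, 5, dimnames = list(measures, measures))
  for (a in measures) for (b in measures) {
    E[a, b] <- length(intersect(top[[a]], top[[b]])) / k
  }
  structure(list(k = as.integer(k), entries = E, top = top,
                 boundary_ties = ties),
            class = "topk_overlap")
}

#' Score centrality measures against ground-truth influential nodes
#'
#' For each measure: how many of the documented influential nodes land in its
#' top k (`hits`), and the reciprocal competition rank of the best-ranked
#' ground-truth node (`reciprocal_rank`; 1 means a ground-truth node is the
#' most central). Eccentricity is inverted before ranking. An empty ground
#' truth yields a report carrying a warning and no scores.
#'
#' @param profile a `centrality_profile` of `annotated$graph`
#' @param annotated an `annotated_graph`
#' @param k top-k cut-off
#' @return a `validation_report`: `dataset`, `k`, `scores` (data.frame with
#'   measure, hits, reciprocal_rank, best_node) or `NULL`, `warnings`
#' @export
score_against_ground_truth <- function(profile, annotated, k = 5L) {
  stopifnot(inherits(annotated, "annotated_graph"))
  gt <- annotated$influential
  warnings <- character(0)
  scores <- NULL
  if (length(gt) == 0L) {
    warnings <- c(warnings, "empty ground-truth set: no recovery scores computed")
  } else {
    measures <- centrality_measures()
    rows <- lapply(measures, function(m) {
      lab <- ranked_labels(profile, m)
      present <- intersect(gt, names(profile$vectors[[m]]$scores))
      if (length(present) < length(gt)) {
        warnings <<- c(warnings, sprintf(
          "%s: %d ground-truth node(s) outside the scored component",
          m, length(gt) - length(present)))
      }
      if (length(present) == 0L) {
        return(data.frame(measure = m, hits = 0L, reciprocal_rank = NA_real_,
                          best_node = NA_character_))
      }
      kk <- min(k, length(lab))
      hits <- length(intersect(lab[seq_len(kk)], present))
      cr <- competition_ranks(profile, m)[present]
      best <- names(cr)[which.min(cr)]
      data.frame(measure = m, hits = hits,
                 reciprocal_rank = 1 / min(cr), best_node = best)
    })
    scores <- do.call(rbind, rows)
  }
  structure(list(dataset = profile$id, k = as.integer(k), scores = scores,
                 influential = gt, warnings = warnings),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> '%s', k = %d, ground truth {%s}\n",
              x$dataset, x$k, paste(x$influential, collapse = ", ")))
  if (!is.null(x$scores)) print(x$scores, row.names = FALSE)
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}
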