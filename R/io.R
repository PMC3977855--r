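#' Read a graph from GML text
#'
#' Parses the GML subset used by the canonical public copies of the classic
#' benchmark networks: a `graph [ ... ]` block containing `node [ id ... ]`
#' records (with optional `label`) and `edge [ source ... target ... ]`
#' records, plus an optional `directed` flag. Directed, reciprocal or
#' duplicate edges are collapsed to undirected simple edges with a warning;
#' self-loops are dropped with a warning. Node identity is the `label` when
#' present, otherwise the stringified `id`. Unrecognised attributes (weights,
#' annotations) are ignored.
#'
#' @param text a GML document: a single string or a character vector of lines
#' @return a [graph_from_edges()] `netgraph`
#' @export
read_gml <- function(text) {
  toks <- gml_tokenize(text)
  doc <- gml_parse_block(toks, 1L, nrow(toks))$items
  gi <- which(vapply(doc, function(it) it$key == "graph" && it$type == "block",
                     logical(1)))
  if (length(gi) != 1L) stop("GML parse error: expected exactly one top-level 'graph [...]' block")
  items <- doc[[gi[1L]]]$value

  directed <- FALSE
  ids <- character(0); labels <- character(0)
  efrom <- character(0); eto <- character(0)
  for (it in items) {
    if (it$key == "directed" && it$type == "scalar") {
      directed <- !identical(it$value, "0")
    } else if (it$key == "node" && it$type == "block") {
      kv <- gml_block_scalars(it$value)
      if (is.na(kv["id"])) {
        stop("GML parse error near line ", it$line, ": node record without 'id'")
      }
      ids <- c(ids, kv[["id"]])
      labels <- c(labels, if (!is.na(kv["label"])) kv[["label"]] else kv[["id"]])
    } else if (it$key == "edge" && it$type == "block") {
      kv <- gml_block_scalars(it$value)
      if (is.na(kv["source"]) || is.na(kv["target"])) {
        stop("GML parse error near line ", it$line,
             ": edge record without 'source'/'target'")
      }
      efrom <- c(efrom, kv[["source"]])
      eto <- c(eto, kv[["target"]])
    }
  }
  if (anyDuplicated(ids)) stop("GML error: duplicate node ids")
  if (anyDuplicated(labels)) stop("GML error: duplicate node labels")
  bad <- !(efrom %in% ids) | !(eto %in% ids)
  if (any(bad)) {
    stop("GML error: edge references unknown node id ",
         paste(unique(c(efrom[bad], eto[bad])), collapse = ", "))
  }
  if (directed) warning("directed GML input collapsed to an undirected simple graph")
  graph_from_edges(
    cbind(labels[match(efrom, ids)], labels[match(eto, ids)]),
    nodes = labels, warn = TRUE
  )
}

# tokenizer: returns matrix-ish data.frame of (token, line)
gml_tokenize <- function(text) {
  lines <- if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else as.character(text)
  toks <- character(0); lns <- integer(0)
  # quoted strings, brackets, and bare atoms
  pat <- '"[^"]*"|\\[|\\]|[^\\s\\[\\]"]+'
  for (i in seq_along(lines)) {
    m <- regmatches(lines[i], gregexpr(pat, lines[i], perl = TRUE))[[1]]
    if (length(m)) {
      toks <- c(toks, m)
      lns <- c(lns, rep.int(i, length(m)))
    }
  }
  data.frame(token = toks, line = lns, stringsAsFactors = FALSE)
}

# recursive-descent parse of a token range into a list of items:
# each item is list(key, type = "scalar"|"block", value, line)
gml_parse_block <- function(toks, from, to) {
  items <- list(); i <- from
  while (i <= to) {
    key <- toks$token[i]; line <- toks$line[i]
    if (key %in% c("[", "]")) {
      stop("GML parse error at line ", line, ": unexpected '", key, "'")
    }
    if (i + 1L > to) stop("GML parse error at line ", line, ": key '", key, "' without value")
    nxt <- toks$token[i + 1L]
    if (nxt == "[") {
      depth <- 1L; j <- i + 2L
      while (j <= to && depth > 0L) {
        if (toks$token[j] == "[") depth <- depth + 1L
        if (toks$token[j] == "]") depth <- depth - 1L
        j <- j + 1L
      }
      if (depth != 0L) stop("GML parse error at line ", line, ": unclosed '[' for key '", key, "'")
      inner <- gml_parse_block(toks, i + 2L, j - 2L)$items
      items[[length(items) + 1L]] <- list(key = key, type = "block", value = inner, line = line)
      i <- j
    } else {
      val <- sub('^"(.*)"$', "\\1", nxt)
      items[[length(items) + 1L]] <- list(key = key, type = "scalar", value = val, line = line)
      i <- i + 2L
    }
  }
  list(items = items)
}

gml_block_scalars <- function(items) {
  keys <- vapply(items, `[[`, character(1), "key")
  vals <- vapply(items, function(it) if (it$type == "scalar") it$value else NA_character_,
                 character(1))
  stats::setNames(vals, keys)[unique(keys)]
}

#' Read a graph from a whitespace edge list
#'
#' One whitespace-separated node pair per line; lines starting with `#` and
#' blank lines are ignored; a single-token line declares an isolated node.
#' Duplicate and reciprocal pairs are collapsed (set semantics) and self-loops
#' dropped, with warnings.
#'
#' @param text a single string or character vector of lines
#' @return a `netgraph`
#' @examples
#' read_edge_list("a b\nb c")
#' @export
read_edge_list <- function(text) {
  lines <- if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else as.character(text)
  keep <- !grepl("^\\s*(#|$)", lines)
  toks <- strsplit(trimws(lines[keep]), "\\s+")
  nt <- lengths(toks)
  if (any(nt > 2L)) {
    bad <- which(keep)[which(nt > 2L)[1L]]
    stop("edge-list parse error at line ", bad, ": expected 1 or 2 tokens, got ", nt[nt > 2L][1L])
  }
  singles <- unlist(toks[nt == 1L], use.names = FALSE)
  pairs <- toks[nt == 2L]
  em <- if (length(pairs)) do.call(rbind, pairs) else matrix(character(0), ncol = 2L)
  nodes_order <- unique(c(unlist(toks, use.names = FALSE)))
  graph_from_edges(em, nodes = nodes_order, warn = TRUE)
}

#' Read a graph from a file, guessing the format
#'
#' @param path file path
#' @param format `"auto"` (by extension: `.gml` vs anything else),
#'   `"gml"`, or `"edgelist"`
#' @return a `netgraph`
#' @export
read_graph_file <- function(path, format = c("auto", "gml", "edgelist")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read input file: ", path)
  txt <- readLines(path, warn = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.gml$", path, ignore.case = TRUE)) "gml" else "edgelist"
  }
  if (format == "gml") read_gml(txt) else read_edge_list(txt)
}

#' Serialise a graph (optionally centrality-annotated) as GML
#'
#' With a profile, every node record carries five numeric attributes
#' (`degree_c`, `betweenness_c`, `closeness_c`, `eccentricity`,
#' `eigenvector_c`), mirroring how the benchmark figures scale and colour
#' nodes by their computed scores. Values are serialised with 12 significant
#' digits. Nodes outside the component on which closeness/eccentricity were
#' computed get `nan`. The output round-trips through [read_gml()]
#' (attributes are ignored on read).
#'
#' @param g a `netgraph`
#' @param profile optional [compute_profile()] result covering all nodes of `g`
#' @param path optional output file; when `NULL` the text is returned
#' @return character vector of GML lines (invisibly, when `path` given)
#' @export
write_gml <- function(g, profile = NULL, path = NULL) {
  n <- n_nodes(g)
  attr_lines <- function(i) character(0)
  if (!is.null(profile)) {
    universe <- names(profile$vectors$degree$scores)
    if (!setequal(universe, g$nodes)) {
      stop("profile node set does not match the graph")
    }
    sc <- function(measure) {
      s <- profile$vectors[[measure]]$scores
      out <- rep(NaN, n)
      out[match(names(s), g$nodes)] <- unname(s)
      out
    }
    cols <- list(degree_c = sc("degree"), betweenness_c = sc("betweenness"),
                 closeness_c = sc("closeness"), eccentricity = sc("eccentricity"),
                 eigenvector_c = sc("eigenvector"))
    attr_lines <- function(i) {
      vapply(names(cols), function(k) {
        sprintf("    %s %s", k, gml_num(cols[[k]][i]))
      }, character(1))
    }
  }
  idx <- seq_len(n)
  out <- c("graph [", "  directed 0")
  for (i in idx) {
    out <- c(out, "  node [", sprintf("    id %d", i),
             sprintf('    label "%s"', gsub('"', "'", g$nodes[i])),
             attr_lines(i), "  ]")
  }
  if (n_edges(g) > 0L) {
    s <- match(g$edges[, 1L], g$nodes)
    t <- match(g$edges[, 2L], g$nodes)
    for (e in seq_along(s)) {
      out <- c(out, "  edge [", sprintf("    source %d", s[e]),
               sprintf("    target %d", t[e]), "  ]")
    }
  }
  out <- c(out, "]")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' @rdname write_gml
#' @export
write_annotated_gml <- function(g, profile, path = NULL) {
  if (is.null(profile)) stop("`profile` is required for annotated output")
  write_gml(g, profile = profile, path = path)
}

gml_num <- function(x) {
  if (is.nan(x)) return("nan")
  sprintf("%.12g", x)
}
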