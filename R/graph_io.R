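#' Network and gene-set file input/output
#'
#' Readers for the STRING-links edge-list dialect, two-column gene-set tables,
#' GMT annotation collections, and symptom-gene bipartite tables.  The network
#' loader applies the confidence-score filter (default: combined score
#' strictly greater than 700) at load time, mirroring the high-confidence
#' cut applied to STRING interactions before module detection.
#'
#' @name graph_io
NULL

read_body_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  list(lines = lines[keep], lineno = which(keep))
}

#' Load a weighted protein interaction network from STRING-links format
#'
#' Expects a whitespace-delimited table with a header naming at least
#' `protein1`, `protein2` and `combined_score` (an integer in 0..1000).
#' Reciprocal duplicate rows (A-B and B-A) collapse to one undirected edge
#' keeping the maximum score; self-loop rows are skipped with a warning;
#' nodes whose every edge is filtered out are dropped.
#'
#' @param path path to the edge-list file.
#' @param min_score score threshold in `[0, 1000]` (default 700).
#' @param strict if `TRUE` (default) keep edges with score `> min_score`;
#'   if `FALSE` use `>= min_score` (the STRING "high confidence >= 700"
#'   convention).
#' @return an undirected [igraph::graph] with a `weight` edge attribute.
#' @examples
#' f <- tempfile()
#' writeLines(c("protein1 protein2 combined_score",
#'              "A B 900", "B C 701", "C D 150"), f)
#' g <- load_string_links(f, min_score = 700)
#' igraph::ecount(g)  # 2
#' @export
load_string_links <- function(path, min_score = 700, strict = TRUE) {
  if (!is.numeric(min_score) || length(min_score) != 1L ||
      min_score < 0 || min_score > 1000) {
    stop_fmt("load_string_links: 'min_score' must be in [0, 1000]")
  }
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop_fmt("load_string_links: '%s' is empty", path)
  header <- strsplit(trimws(lines[[1L]]), "[ \t]+")[[1L]]
  needed <- c("protein1", "protein2", "combined_score")
  missing <- setdiff(needed, header)
  if (length(missing)) {
    stop_fmt("load_string_links: missing column(s): %s",
             paste(missing, collapse = ", "))
  }
  idx <- match(needed, header)
  body <- lines[-1L]
  nonblank <- which(!grepl("^\\s*(#|$)", body))
  if (!length(nonblank)) {
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  fields <- strsplit(trimws(body[nonblank]), "[ \t]+")
  nf <- lengths(fields)
  bad <- which(nf < length(header))
  if (length(bad)) {
    stop_fmt("load_string_links: line %d: expected %d fields, found %d",
             nonblank[bad[1L]] + 1L, length(header), nf[bad[1L]])
  }
  m <- matrix(unlist(lapply(fields, `[`, idx)), ncol = 3L, byrow = TRUE)
  p1 <- m[, 1L]; p2 <- m[, 2L]
  score <- suppressWarnings(as.numeric(m[, 3L]))
  bad <- which(is.na(score) | score != floor(score))
  if (length(bad)) {
    stop_fmt("load_string_links: line %d: combined_score '%s' is not an integer",
             nonblank[bad[1L]] + 1L, m[bad[1L], 3L])
  }
  loops <- p1 == p2
  if (any(loops)) {
    warn_fmt("load_string_links: skipped %d self-loop row(s)", sum(loops))
    p1 <- p1[!loops]; p2 <- p2[!loops]; score <- score[!loops]
  }
  keep <- if (strict) score > min_score else score >= min_score
  p1 <- p1[keep]; p2 <- p2[keep]; score <- score[keep]
  if (!length(p1)) return(igraph::make_empty_graph(0, directed = FALSE))
  a <- pmin(p1, p2); b <- pmax(p1, p2)
  key <- paste(a, b, sep = "\r")
  w <- tapply(score, key, max)
  ab <- do.call(rbind, strsplit(names(w), "\r", fixed = TRUE))
  g <- igraph::graph_from_data_frame(
    data.frame(from = ab[, 1L], to = ab[, 2L],
               weight = as.numeric(w), stringsAsFactors = FALSE),
    directed = FALSE)
  g
}

#' Write a weighted graph in STRING-links format
#'
#' Inverse of [load_string_links()]: reloading the file with `min_score = 0`
#' recovers the identical edge set and weights.
#'
#' @param graph undirected igraph with a `weight` edge attribute.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_string_links <- function(graph, path) {
  stopifnot(inherits(graph, "igraph"))
  el <- igraph::as_edgelist(graph)
  w <- igraph::E(graph)$weight %||% rep(1, nrow(el))
  lines <- c("protein1\tprotein2\tcombined_score",
             if (nrow(el)) sprintf("%s\t%s\t%d", el[, 1L], el[, 2L],
                                   as.integer(round(w))))
  writeLines(lines, path)
  invisible(path)
}

parse_two_col <- function(path, what) {
  b <- read_body_lines(path)
  if (!length(b$lines)) {
    warn_fmt("%s: '%s' has no data rows", what, path)
    return(NULL)
  }
  fields <- strsplit(b$lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  ncol <- nf[[1L]]
  if (!ncol %in% 1:2) {
    stop_fmt("%s: line %d: expected 1 or 2 tab-separated fields, found %d",
             what, b$lineno[1L], ncol)
  }
  bad <- which(nf != ncol)
  if (length(bad)) {
    stop_fmt("%s: line %d: expected %d field(s), found %d",
             what, b$lineno[bad[1L]], ncol, nf[bad[1L]])
  }
  m <- matrix(trimws(unlist(fields)), ncol = ncol, byrow = TRUE)
  if (any(!nzchar(m))) {
    bad <- which(rowSums(!nzchar(m)) > 0)[1L]
    stop_fmt("%s: line %d: empty field", what, b$lineno[bad])
  }
  m
}

#' Load named gene sets from a two-column table
#'
#' Tab-separated, UTF-8, `#` comment lines allowed: column 1 is the set name,
#' column 2 the gene identifier.  A single-column file is interpreted as one
#' unnamed set (named `"unnamed"`).  Duplicate (name, gene) rows are
#' deduplicated; identifiers are whitespace-trimmed.
#'
#' @param path path to the table.
#' @param source source tag applied to every returned set
#'   (see [gene_set_sources]).
#' @return list of [gene_set()] objects, in order of first appearance.
#' @export
load_gene_sets <- function(path, source = "disease") {
  m <- parse_two_col(path, "load_gene_sets")
  if (is.null(m)) return(list())
  if (ncol(m) == 1L) {
    return(list(gene_set("unnamed", m[, 1L], source = source)))
  }
  sets <- split(m[, 2L], factor(m[, 1L], levels = unique(m[, 1L])))
  unname(Map(function(nm, genes) gene_set(nm, genes, source = source),
             names(sets), sets))
}

#' Load an annotation collection in GMT format
#'
#' One set per line: name, description (discarded), then one or more genes,
#' all tab-separated.  Duplicate genes within a line are deduplicated.
#'
#' @param path path to the `.gmt` file.
#' @return list of [gene_set()] objects with source `"annotation"`.
#' @export
load_gmt <- function(path) {
  b <- read_body_lines(path)
  if (!length(b$lines)) return(list())
  fields <- strsplit(b$lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 3L)
  if (length(bad)) {
    stop_fmt("load_gmt: line %d: expected >= 3 tab-separated fields, found %d",
             b$lineno[bad[1L]], nf[bad[1L]])
  }
  lapply(fields, function(f) {
    gene_set(f[[1L]], f[-(1:2)], source = "annotation")
  })
}

#' Load a symptom-gene bipartite map from a two-column table
#'
#' Column 1 is the symptom term, column 2 a gene associated with it.
#'
#' @param path path to the table.
#' @return a [bipartite_map()].
#' @export
load_bipartite <- function(path) {
  m <- parse_two_col(path, "load_bipartite")
  if (is.null(m) || ncol(m) != 2L) {
    stop_fmt("load_bipartite: '%s' must have two tab-separated columns", path)
  }
  bipartite_map(split(m[, 2L], factor(m[, 1L], levels = unique(m[, 1L]))))
}

#' Write a bipartite map / gene sets as two-column tables
#' @param map a [bipartite_map()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bipartite <- function(map, path) {
  stopifnot(inherits(map, "bipartite_map"))
  lines <- unlist(Map(function(s, g) paste(s, g, sep = "\t"), names(map), map),
                  use.names = FALSE)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_bipartite
#' @param sets list of [gene_set()] objects (or a single one).
#' @export
write_gene_sets <- function(sets, path) {
  if (inherits(sets, "gene_set")) sets <- list(sets)
  lines <- unlist(lapply(sets, function(s) paste(s$name, s$members, sep = "\t")),
                  use.names = FALSE)
  writeLines(lines, path)
  invisible(path)
}
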