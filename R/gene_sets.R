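#' Gene sets and symptom-gene bipartite maps
#'
#' A `gene_set` is a named, deduplicated collection of gene (or protein)
#' identifiers carrying a source tag.  Identifiers are opaque strings: no
#' namespace mapping (Ensembl vs. symbol vs. STRING id) is attempted, they are
#' assumed pre-reconciled across inputs.
#'
#' @name gene_sets
NULL

#' Valid source tags for a gene set
#' @export
gene_set_sources <- c("disease", "symptom", "target_drug",
                      "target_formula_BS", "target_formula_PS", "annotation")

#' Construct a gene set
#'
#' @param name non-empty set label.
#' @param members character vector of gene identifiers; whitespace is trimmed,
#'   duplicates and empty strings are dropped.
#' @param source one of [gene_set_sources].
#' @return an object of class `gene_set` with fields `name`, `source`,
#'   `members`.
#' @examples
#' gene_set("S1", c("TP53", "ACE", "ACE"))
#' @export
gene_set <- function(name, members = character(), source = "disease") {
  if (!is.character(name) || length(name) != 1L || is.na(name) || !nzchar(name)) {
    stop_fmt("gene_set: 'name' must be a single non-empty string")
  }
  source <- match.arg(source, gene_set_sources)
  members <- trimws(as.character(members))
  members <- unique(members[nzchar(members) & !is.na(members)])
  structure(list(name = name, source = source, members = members),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s [%s]: %d genes\n",
              x$name, x$source, length(x$members)))
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$members)

as_members <- function(x, arg = "x") {
  if (inherits(x, "gene_set")) return(x$members)
  if (is.character(x)) return(unique(trimws(x[nzchar(x)])))
  stop_fmt("'%s' must be a gene_set or character vector", arg)
}

#' Construct a symptom-gene bipartite map
#'
#' Maps symptom terms to the gene sets associated with them (the structure of
#' symptom-disease-gene resources such as HSDN).  Symptoms with empty gene
#' sets are disallowed.
#'
#' @param associations named list; names are symptom terms, elements character
#'   vectors of gene identifiers.
#' @return object of class `bipartite_map` (a named list of character vectors).
#' @export
bipartite_map <- function(associations) {
  if (!is.list(associations) || is.null(names(associations)) ||
      any(!nzchar(names(associations)))) {
    stop_fmt("bipartite_map: 'associations' must be a named list of gene vectors")
  }
  out <- lapply(associations, function(g) {
    g <- trimws(as.character(g))
    unique(g[nzchar(g) & !is.na(g)])
  })
  if (any(lengths(out) == 0L)) {
    stop_fmt("bipartite_map: symptom(s) %s map to an empty gene set",
             paste(names(out)[lengths(out) == 0L], collapse = ", "))
  }
  structure(out, class = "bipartite_map")
}

#' Union of all gene sets in a bipartite map
#'
#' @param map a [bipartite_map()].
#' @return character vector: the map's gene universe.
#' @export
flatten_genes <- function(map) {
  if (!inherits(map, "bipartite_map")) stop_fmt("'map' must be a bipartite_map")
  sort(unique(unlist(map, use.names = FALSE)))
}

#' @export
print.bipartite_map <- function(x, ...) {
  cat(sprintf("<bipartite_map> %d symptoms, %d distinct genes\n",
              length(x), length(flatten_genes(x))))
  invisible(x)
}
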