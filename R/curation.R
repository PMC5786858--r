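#' Disease-gene source merging with a provenance ledger
#'
#' Curating a disease gene list means unioning several sources (a curated
#' database, literature mining, OMIM/GWAS) while accounting for how much each
#' source overlaps the ones before it.  `merge_sources` reproduces that
#' arithmetic: per-source sizes, all pairwise overlaps, genes newly
#' contributed by each source in the stated order, and the union size.
#'
#' @name gene_curation
NULL

#' Merge gene-set sources into one union with an overlap ledger
#'
#' @param sets ordered list of [gene_set()] objects (order matters only for
#'   the `new_per_source` accounting; union size and pairwise overlaps are
#'   order-insensitive).
#' @return list with:
#'   \describe{
#'     \item{union}{a [gene_set()] of all members; its `gene_sources`
#'       attribute is a data.frame mapping each gene to the comma-joined
#'       names of the sources containing it.}
#'     \item{ledger}{a `source_ledger`: `per_source_sizes` (named integer),
#'       `pairwise_overlaps` (data.frame `source_a`, `source_b`, `overlap`),
#'       `new_per_source` (named integer, sums to `union_size`), and
#'       `union_size`.}
#'   }
#' @examples
#' a <- gene_set("db", c("g1", "g2"))
#' b <- gene_set("lit", c("g2", "g3"))
#' merge_sources(list(a, b))$ledger$union_size  # 3
#' @export
merge_sources <- function(sets) {
  if (!is.list(sets) || !length(sets) ||
      !all(vapply(sets, inherits, logical(1), "gene_set"))) {
    stop_fmt("merge_sources: 'sets' must be a non-empty list of gene_set objects")
  }
  nms <- vapply(sets, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop_fmt("merge_sources: duplicate source names")
  members <- lapply(sets, `[[`, "members")
  names(members) <- nms

  sizes <- lengths(members)
  running <- character()
  new_per_source <- integer(length(sets))
  for (s in seq_along(sets)) {
    new_per_source[s] <- length(setdiff(members[[s]], running))
    running <- union(running, members[[s]])
  }
  names(new_per_source) <- nms

  pairs <- if (length(sets) > 1L) utils::combn(seq_along(sets), 2L) else
    matrix(integer(), nrow = 2)
  overlaps <- data.frame(
    source_a = nms[pairs[1L, ]],
    source_b = nms[pairs[2L, ]],
    overlap = if (ncol(pairs)) apply(pairs, 2L, function(p)
      length(intersect(members[[p[1L]]], members[[p[2L]]]))) else integer(),
    stringsAsFactors = FALSE)

  union_set <- gene_set(paste(nms, collapse = "+"), running,
                        source = sets[[1L]]$source)
  gene_sources <- data.frame(
    gene = union_set$members,
    sources = vapply(union_set$members, function(g)
      paste(nms[vapply(members, function(m) g %in% m, logical(1))],
            collapse = ","), character(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  attr(union_set, "gene_sources") <- gene_sources

  ledger <- structure(
    list(per_source_sizes = sizes,
         pairwise_overlaps = overlaps,
         new_per_source = new_per_source,
         union_size = length(union_set$members)),
    class = "source_ledger")
  list(union = union_set, ledger = ledger)
}

#' @export
print.source_ledger <- function(x, ...) {
  cat("<source_ledger>\n  sizes: ",
      paste(sprintf("%s=%d", names(x$per_source_sizes), x$per_source_sizes),
            collapse = ", "),
      "\n  new per source: ",
      paste(sprintf("%s=%d", names(x$new_per_source), x$new_per_source),
            collapse = ", "),
      sprintf("\n  union: %d\n", x$union_size), sep = "")
  invisible(x)
}

#' Exclusion accounting for manually screened candidates
#'
#' When candidate genes are excluded by manual screening, some exclusions are
#' ambiguous (gene symbols that usually mean something else, e.g. "DBP" as
#' diastolic blood pressure) and are potential false negatives.  Returns the
#' kept set and the ambiguous fraction of the exclusions.
#'
#' @param candidates a [gene_set()] or character vector of screened genes.
#' @param excluded subset of `candidates` that was excluded.
#' @param ambiguous subset of `excluded` flagged ambiguous (caller-supplied
#'   metadata).
#' @return list with `kept` (a [gene_set()]) and `ambiguous_fraction`
#'   (`|ambiguous| / |excluded|`, rounded to 4 decimals; 0 when nothing was
#'   excluded).
#' @export
exclusion_report <- function(candidates, excluded, ambiguous = character()) {
  cand <- as_members(candidates, "candidates")
  excl <- as_members(excluded, "excluded")
  amb <- as_members(ambiguous, "ambiguous")
  if (length(setdiff(excl, cand))) {
    stop_fmt("exclusion_report: 'excluded' is not a subset of 'candidates'")
  }
  if (length(setdiff(amb, excl))) {
    stop_fmt("exclusion_report: 'ambiguous' is not a subset of 'excluded'")
  }
  kept <- gene_set(
    if (inherits(candidates, "gene_set")) candidates$name else "kept",
    setdiff(cand, excl),
    source = if (inherits(candidates, "gene_set")) candidates$source else "disease")
  frac <- if (length(excl)) round(length(amb) / length(excl), 4) else 0
  list(kept = kept, ambiguous_fraction = frac)
}
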