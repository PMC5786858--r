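#' Hypergeometric module enrichment and module-selection rules
#'
#' A module of size `n` inside a background universe of `N` genes, `K` of
#' which are annotated (e.g. disease-associated), overlapping the annotation
#' in `k` genes, is scored by the hypergeometric upper tail `P(X >= k)`.
#' Disease modules are the modules passing a joint criterion: raw p-value
#' below `alpha` (0.01) and annotated-gene proportion `k/n` at least
#' `rr_multiplier` (3) times the background proportion `K/N` (the relative
#' risk filter).  Syndrome modules are disease modules additionally enriched
#' (p < alpha) for symptom-associated genes.
#'
#' @name set_enrichment
NULL

#' Hypergeometric upper-tail probability P(X >= k)
#'
#' Drawing `n` items without replacement from an urn of `N` containing `K`
#' marked items, the probability of at least `k` marked draws.  Evaluated via
#' the numerically stable survival function (log-space internally); always in
#' `(0, 1]` and exactly 1 when `k = 0`.
#'
#' @param k observed overlap count.
#' @param K annotated genes in the background.
#' @param n module (query) size within the background.
#' @param N background universe size.
#' @return the upper-tail p-value; vectorized over its arguments.
#' @examples
#' hypergeom_upper_tail(4, 5, 4, 10)  # choose(5,4)/choose(10,4) = 5/210
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  bad <- !vapply(list(k, K, n, N), function(x)
    all(is.numeric(x)) && !anyNA(x) && all(x >= 0) && all(x == floor(x)),
    logical(1))
  if (any(bad)) stop_fmt("hypergeom_upper_tail: counts must be non-negative integers")
  if (any(K > N) || any(n > N) || any(k > pmin(K, n))) {
    stop_fmt("hypergeom_upper_tail: need k <= min(K, n), n <= N, K <= N")
  }
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  pmin(pmax(p, 0), 1)
}

#' Construct an enrichment background
#'
#' The urn the hypergeometric test assumes.  The default pipeline policy is
#' `covered_modules`: the universe is the union of all potential disease
#' modules' members, matching background proportions of the form
#' K / (proteins covered by potential modules).
#'
#' @param universe character vector of gene identifiers (non-empty).
#' @param policy one of `"covered_modules"`, `"whole_graph"`, `"custom"`.
#' @return object of class `enrich_background`.
#' @export
background <- function(universe,
                       policy = c("covered_modules", "whole_graph", "custom")) {
  policy <- match.arg(policy)
  universe <- unique(as.character(universe))
  universe <- universe[nzchar(universe)]
  if (!length(universe)) stop_fmt("background: empty universe")
  structure(list(policy = policy, universe = sort(universe)),
            class = "enrich_background")
}

#' @export
print.enrich_background <- function(x, ...) {
  cat(sprintf("<enrich_background> policy=%s, N=%d\n",
              x$policy, length(x$universe)))
  invisible(x)
}

#' Modules containing at least one annotated gene
#'
#' Flags "potential disease modules": modules whose membership intersects the
#' gene set.  Also returns the covered universe (union of those modules'
#' members), the default enrichment background.
#'
#' @param partition a `ppi_partition`.
#' @param genes a [gene_set()] or character vector.
#' @return list with `modules` (integer labels) and `universe` (character).
#' @export
select_potential_modules <- function(partition, genes) {
  stopifnot(inherits(partition, "ppi_partition"))
  g <- as_members(genes, "genes")
  if (!length(g)) stop_fmt("select_potential_modules: empty gene set")
  mm <- module_members(partition)
  hit <- vapply(mm, function(m) any(m %in% g), logical(1))
  if (!any(hit)) {
    warn_fmt("select_potential_modules: no module contains an annotated gene")
    return(list(modules = integer(), universe = character()))
  }
  list(modules = as.integer(names(mm)[hit]),
       universe = sort(unique(unlist(mm[hit], use.names = FALSE))))
}

enrichment_record <- function(module, k, n, K, N, p_value,
                              alpha = 0.01, rr_multiplier = 3.0) {
  K <- rep_len(K, length(module))
  N <- rep_len(N, length(module))
  prop <- ifelse(n > 0, k / n, NA_real_)
  bg <- K / N
  data.frame(module = as.integer(module), k = as.integer(k), n = as.integer(n),
             K = as.integer(K), N = as.integer(N), p_value = p_value,
             proportion = prop, background_proportion = bg,
             is_potential = k >= 1L,
             passes_p = p_value < alpha,
             passes_rr = prop >= rr_multiplier * bg,
             row.names = NULL)
}

#' Build enrichment records directly from counts
#'
#' Constructor for the per-module enrichment table when counts (and
#' optionally p-values, e.g. from a published table) are already known;
#' [enrich_modules()] produces the same shape from a partition.
#'
#' @param module integer module labels.
#' @param k,n per-module overlap and size.
#' @param K,N background annotated count and universe size.
#' @param p_value optional known p-values; computed via
#'   [hypergeom_upper_tail()] when `NULL`.
#' @param alpha,rr_multiplier thresholds used for the convenience flags.
#' @return a `module_enrichment` data.frame.
#' @export
module_enrichment <- function(module, k, n, K, N, p_value = NULL,
                              alpha = 0.01, rr_multiplier = 3.0) {
  if (is.null(p_value)) p_value <- hypergeom_upper_tail(k, K, n, N)
  out <- enrichment_record(module, k, n, K, N, p_value, alpha, rr_multiplier)
  class(out) <- c("module_enrichment", "data.frame")
  out
}

#' Hypergeometric enrichment of a gene set across modules
#'
#' For each tested module, computes `n = |module members in universe|`,
#' `k = |module members in gene set|`, with `N = |universe|` and
#' `K = |gene set in universe|`, and the upper-tail p-value.  Genes outside
#' the background universe are dropped before counting (with a logged count)
#' so the urn stays coherent; modules with `n = 0` after restriction are
#' excluded with a warning.
#'
#' @param partition a `ppi_partition`.
#' @param genes a [gene_set()] or character vector.
#' @param background an [background()] object.
#' @param modules integer labels of the modules to test; `NULL` (default)
#'   tests the potential modules (overlap `k >= 1`).
#' @param alpha,rr_multiplier thresholds recorded in the convenience flags.
#' @return a `module_enrichment` data.frame sorted by ascending p-value
#'   (ties by module label).
#' @export
enrich_modules <- function(partition, genes, background, modules = NULL,
                           alpha = 0.01, rr_multiplier = 3.0) {
  stopifnot(inherits(partition, "ppi_partition"),
            inherits(background, "enrich_background"))
  U <- background$universe
  if (!length(U)) stop_fmt("enrich_modules: empty background universe")
  g <- as_members(genes, "genes")
  g_in <- intersect(g, U)
  dropped <- length(g) - length(g_in)
  if (dropped > 0) {
    message(sprintf("enrich_modules: dropped %d gene(s) outside the background universe",
                    dropped))
  }
  mm <- module_members(partition)
  N <- length(U)
  K <- length(g_in)
  ns <- vapply(mm, function(m) length(intersect(m, U)), integer(1))
  ks <- vapply(mm, function(m) length(intersect(m, g_in)), integer(1))
  labels <- as.integer(names(mm))
  if (is.null(modules)) {
    keep <- ks >= 1L
  } else {
    unknown <- setdiff(modules, labels)
    if (length(unknown)) {
      stop_fmt("enrich_modules: unknown module label(s): %s",
               paste(unknown, collapse = ", "))
    }
    keep <- labels %in% modules
  }
  if (any(keep & ns == 0L)) {
    warn_fmt("enrich_modules: excluded %d module(s) empty after universe restriction",
             sum(keep & ns == 0L))
    keep <- keep & ns > 0L
  }
  if (!any(keep)) {
    warn_fmt("enrich_modules: no module to test")
    return(module_enrichment(integer(), integer(), integer(),
                             K, N, numeric()))
  }
  p <- hypergeom_upper_tail(ks[keep], K, ns[keep], N)
  out <- module_enrichment(labels[keep], ks[keep], ns[keep], K, N, p,
                           alpha = alpha, rr_multiplier = rr_multiplier)
  out[order(out$p_value, out$module), , drop = FALSE]
}

#' Select disease modules: joint p-value and relative-risk criterion
#'
#' Keeps records with `p_value < alpha` AND
#' `proportion >= rr_multiplier * background_proportion`.  Setting
#' `rr_multiplier = 0` reduces to the pure p-threshold rule; `alpha = 1`
#' reduces to the pure relative-risk rule.
#'
#' @param records a `module_enrichment` data.frame.
#' @param alpha raw p-value threshold (default 0.01; no multiple-testing
#'   correction is applied at this stage).
#' @param rr_multiplier relative-risk multiplier (default 3).
#' @return the selected rows, input order preserved.
#' @export
select_disease_modules <- function(records, alpha = 0.01, rr_multiplier = 3.0) {
  stopifnot(is.data.frame(records),
            all(c("module", "p_value", "proportion", "background_proportion")
                %in% names(records)))
  keep <- records$p_value < alpha &
    records$proportion >= rr_multiplier * records$background_proportion
  records[which(keep), , drop = FALSE]
}

#' Select syndrome modules among the disease modules
#'
#' A syndrome module is a module enriched for symptom-associated genes
#' (p < alpha) that is simultaneously a disease module.  `symptom_records`
#' must have been computed against the same background as the disease run.
#'
#' @param symptom_records `module_enrichment` records for the symptom gene
#'   union.
#' @param disease_modules integer labels, or the data.frame returned by
#'   [select_disease_modules()].
#' @param alpha symptom p-value threshold (default 0.01).
#' @return the selected symptom rows.
#' @export
select_syndrome_modules <- function(symptom_records, disease_modules,
                                    alpha = 0.01) {
  stopifnot(is.data.frame(symptom_records))
  if (is.data.frame(disease_modules)) disease_modules <- disease_modules$module
  keep <- symptom_records$p_value < alpha &
    symptom_records$module %in% disease_modules
  symptom_records[which(keep), , drop = FALSE]
}
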