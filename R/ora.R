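#' Over-representation analysis with Bonferroni correction
#'
#' Tests a query gene list (typically one module) against every term of an
#' annotation collection (GO/KEGG-style GMT) by the hypergeometric upper
#' tail, then applies a Bonferroni correction whose factor counts only the
#' terms actually testable in the background (non-empty after universe
#' restriction), the "number of tests performed" reading of Bonferroni.
#'
#' @param query a [gene_set()] or character vector of query genes.
#' @param collection list of annotation [gene_set()] objects (e.g. from
#'   [load_gmt()]).
#' @param background an [background()] object; query and terms are restricted
#'   to its universe before counting.
#' @param alpha corrected-p-value significance threshold (default 0.01).
#' @return data.frame of class `ora_result` with columns `term`, `k`, `n`,
#'   `K`, `N`, `p_value`, `cpv` (`min(1, p * n_tests)`) and `significant`
#'   (`cpv < alpha`), sorted by ascending `cpv` with ties by term name.
#'   Terms with zero overlap are still reported (`k = 0`, `p = 1`).
#' @examples
#' bg <- background(sprintf("g%02d", 1:40), policy = "custom")
#' terms <- list(gene_set("T1", sprintf("g%02d", 1:8), source = "annotation"))
#' ora(sprintf("g%02d", 1:10), terms, bg)
#' @export
ora <- function(query, collection, background, alpha = 0.01) {
  stopifnot(inherits(background, "enrich_background"))
  U <- background$universe
  if (!length(U)) stop_fmt("ora: empty background universe")
  if (!length(collection)) {
    warn_fmt("ora: empty annotation collection")
    out <- data.frame(term = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), p_value = numeric(),
                      cpv = numeric(), significant = logical())
    class(out) <- c("ora_result", "data.frame")
    return(out)
  }
  if (!all(vapply(collection, inherits, logical(1), "gene_set"))) {
    stop_fmt("ora: 'collection' must be a list of gene_set objects")
  }
  q <- intersect(as_members(query, "query"), U)
  N <- length(U)
  n <- length(q)
  terms <- vapply(collection, `[[`, character(1), "name")
  Ks <- vapply(collection, function(s) length(intersect(s$members, U)), integer(1))
  ks <- vapply(collection, function(s) length(intersect(s$members, q)), integer(1))
  n_tests <- sum(Ks > 0L)
  p <- rep(1, length(collection))
  testable <- Ks > 0L
  if (any(testable)) {
    p[testable] <- hypergeom_upper_tail(ks[testable], Ks[testable], n, N)
  }
  cpv <- pmin(1, p * max(n_tests, 1L))
  out <- data.frame(term = terms, k = ks, n = n, K = Ks, N = N,
                    p_value = p, cpv = cpv, significant = cpv < alpha,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$cpv, out$term), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ora_result", "data.frame")
  out
}
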