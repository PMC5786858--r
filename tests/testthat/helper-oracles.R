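# Independent oracles and fixture builders shared across the suite.
# Oracles are deliberately written differently from the implementation paths
# they check (enumeration / pair counting / direct set algebra).

# hypergeometric upper tail by direct enumeration of the pmf via lchoose
hyper_tail_oracle <- function(k, K, n, N) {
  js <- k:min(K, n)
  sum(exp(lchoose(K, js) + lchoose(N - K, n - js) - lchoose(N, n)))
}

# ARI by O(n^2) pair counting (no contingency-table shortcut)
ari_pairs_oracle <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) b <- b[names(a)]
  n <- length(a)
  s11 <- s00 <- s10 <- s01 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) s11 <- s11 + 1
    else if (!sa && !sb) s00 <- s00 + 1
    else if (sa) s10 <- s10 + 1
    else s01 <- s01 + 1
  }
  tot <- s11 + s00 + s10 + s01
  exp11 <- (s11 + s10) * (s11 + s01) / tot
  (s11 - exp11) / ((2 * s11 + s10 + s01) / 2 - exp11)
}

# all set partitions of 1..n (restricted growth strings); n small
all_partitions <- function(n) {
  out <- list()
  rec <- function(assign, maxlab) {
    i <- length(assign) + 1L
    if (i > n) { out[[length(out) + 1L]] <<- assign; return() }
    for (lab in seq_len(maxlab + 1L)) {
      rec(c(assign, lab), max(maxlab, lab))
    }
  }
  rec(integer(), 0L)
  out
}

# max modularity over all partitions whose communities are connected
brute_best_q <- function(graph) {
  n <- igraph::vcount(graph)
  stopifnot(n <= 9)
  best <- -Inf
  adj <- igraph::as_adjacency_matrix(graph, sparse = FALSE)
  nm <- igraph::V(graph)$name
  for (p in all_partitions(n)) {
    ok <- all(vapply(split(seq_len(n), p), function(ix) {
      if (length(ix) == 1L) return(TRUE)
      sub <- igraph::induced_subgraph(graph, ix)
      igraph::is_connected(sub)
    }, logical(1)))
    if (!ok) next
    q <- modularity_q(graph, stats::setNames(p, nm))
    if (q > best) best <- q
  }
  best
}

# small deterministic toy graphs
two_triangles <- function() {
  igraph::make_graph(~ a - b, b - c, c - a, d - e, e - f, f - d)
}

clique_ring <- function(k = 5, cliques = 4) {
  tags <- letters[seq_len(cliques)]
  el <- do.call(rbind, lapply(tags, function(t)
    t(utils::combn(paste0(t, seq_len(k)), 2))))
  bridges <- cbind(paste0(tags, 1),
                   paste0(tags[c(2:cliques, 1)], 2))
  igraph::graph_from_edgelist(rbind(el, bridges), directed = FALSE)
}

write_lines_tmp <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

string_links_fixture <- function(rows) {
  write_lines_tmp(c("protein1\tprotein2\tcombined_score", rows))
}
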