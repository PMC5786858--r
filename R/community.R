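#' Topological module detection by weighted-modularity maximization
#'
#' Implements the two-phase greedy modularity algorithm of Blondel et al.
#' (BGLL / "Louvain"): repeated sweeps of single-node moves that accept the
#' move with the largest positive modularity gain, followed by aggregation of
#' communities into super-nodes, iterated until a full pass improves
#' modularity by less than `1e-12`.  Node sweep order is a seeded
#' Fisher-Yates shuffle redrawn each pass, ties among equal-gain candidate
#' communities break to the lowest label, so identical `(graph, seed,
#' resolution)` inputs give bit-identical partitions.
#'
#' @name community_detection
NULL

# edge arrays + per-node strength for a (possibly aggregated) graph
# i, j: 1-based endpoint indices; w: weights; self: per-node self-loop weight
strengths_of <- function(n, i, j, w, self) {
  agg <- rowsum(c(w, w, 2 * self), group = c(i, j, seq_len(n)))
  k <- numeric(n)
  k[as.integer(rownames(agg))] <- agg[, 1L]
  k
}

q_of <- function(n, i, j, w, self, comm, resolution = 1) {
  W <- sum(w) + sum(self)
  if (W <= 0) stop_fmt("modularity: graph has no edges")
  k <- strengths_of(n, i, j, w, self)
  sc <- rowsum(k, comm)
  intra <- comm[i] == comm[j]
  wc_tab <- rowsum(c(w[intra], self), c(comm[i][intra], comm))
  sum(wc_tab) / W - resolution * sum((sc / (2 * W))^2)
}

graph_arrays <- function(graph) {
  n <- igraph::vcount(graph)
  el <- igraph::as_edgelist(graph, names = FALSE)
  w <- igraph::E(graph)$weight %||% rep(1, nrow(el))
  list(n = n, i = el[, 1L], j = el[, 2L], w = as.numeric(w),
       self = numeric(n))
}

#' Weighted Newman-Girvan modularity of a partition
#'
#' Computes `Q = sum_c [ W_c / W - (S_c / 2W)^2 ]` where `W` is the total
#' edge weight, `W_c` the intra-community weight and `S_c` the total strength
#' of community `c`.  Pure function; edge weights are used as-is (modularity
#' is invariant to weight rescaling).
#'
#' @param graph undirected igraph with optional `weight` edge attribute and
#'   at least one edge.
#' @param membership community labels: a vector named by node name (or, for
#'   unnamed graphs, aligned with vertex order) covering every node.
#' @return modularity Q in `[-0.5, 1]`.
#' @examples
#' g <- igraph::make_graph(~ a - b, b - c, c - a, d - e, e - f, f - d)
#' modularity_q(g, c(a = 1, b = 1, c = 1, d = 2, e = 2, f = 2))  # 0.5
#' @export
modularity_q <- function(graph, membership) {
  stopifnot(inherits(graph, "igraph"))
  n <- igraph::vcount(graph)
  if (n == 0L) stop_fmt("modularity: empty graph")
  if (igraph::ecount(graph) == 0L) stop_fmt("modularity: graph has no edges")
  nm <- igraph::V(graph)$name
  if (!is.null(nm) && !is.null(names(membership))) {
    miss <- setdiff(nm, names(membership))
    if (length(miss)) {
      stop_fmt("modularity: node(s) missing from membership: %s",
               paste(utils::head(miss, 5L), collapse = ", "))
    }
    membership <- membership[nm]
  } else if (length(membership) != n) {
    stop_fmt("modularity: membership must cover all %d nodes", n)
  }
  if (anyNA(membership)) stop_fmt("modularity: membership contains NA")
  a <- graph_arrays(graph)
  q_of(a$n, a$i, a$j, a$w, a$self, as.integer(factor(membership)))
}

# one local-move phase; returns community assignment (1..n labels, not dense)
louvain_one_level <- function(n, i, j, w, self, resolution) {
  k <- strengths_of(n, i, j, w, self)
  twoW <- 2 * (sum(w) + sum(self))
  ei <- c(i, j); ej <- c(j, i); ew <- c(w, w)
  f <- factor(ei, levels = seq_len(n))
  nb <- split(ej, f)
  nw <- split(ew, f)
  comm <- seq_len(n)
  tot <- k
  repeat {
    moved <- FALSE
    for (v in sample.int(n)) {            # fresh Fisher-Yates shuffle per pass
      nv <- nb[[v]]
      if (!length(nv)) next
      cv <- comm[v]
      agg <- rowsum(nw[[v]], comm[nv])
      cand <- as.integer(rownames(agg))
      lvc <- agg[, 1L]
      if (!(cv %in% cand)) { cand <- c(cand, cv); lvc <- c(lvc, 0) }
      o <- order(cand)
      cand <- cand[o]; lvc <- lvc[o]
      tot[cv] <- tot[cv] - k[v]           # remove v before evaluating gains
      gain <- lvc - resolution * k[v] * tot[cand] / twoW
      best_i <- which.max(gain)           # first max = lowest label wins ties
      best <- cand[best_i]
      if (best != cv && gain[best_i] > gain[match(cv, cand)]) {
        comm[v] <- best
        tot[best] <- tot[best] + k[v]
        moved <- TRUE
      } else {
        tot[cv] <- tot[cv] + k[v]
      }
    }
    if (!moved) break
  }
  comm
}

aggregate_level <- function(n, i, j, w, self, comm) {
  dense <- match(comm, sort(unique(comm)))
  C <- max(dense)
  ci <- dense[i]; cj <- dense[j]
  intra <- ci == cj
  newself <- numeric(C)
  if (any(intra)) {
    s <- rowsum(w[intra], ci[intra])
    newself[as.integer(rownames(s))] <- s[, 1L]
  }
  if (any(self > 0)) {
    s <- rowsum(self, dense)
    newself[as.integer(rownames(s))] <- newself[as.integer(rownames(s))] + s[, 1L]
  }
  if (any(!intra)) {
    a <- pmin(ci, cj)[!intra]
    b <- pmax(ci, cj)[!intra]
    key <- (a - 1) * C + b
    s <- rowsum(w[!intra], key)
    kk <- as.numeric(rownames(s))
    ni <- as.integer((kk - 1) %/% C + 1)
    nj <- as.integer((kk - 1) %% C + 1)
    nw <- s[, 1L]
  } else {
    ni <- integer(); nj <- integer(); nw <- numeric()
  }
  list(n = C, i = ni, j = nj, w = nw, self = newself, dense = dense)
}

#' Partition a weighted graph into topological modules (Louvain/BGLL)
#'
#' @param graph non-empty undirected igraph; a `weight` edge attribute is
#'   used if present.  Disconnected graphs are allowed.
#' @param seed integer seed driving the per-pass node shuffles (mandatory:
#'   the algorithm's local optima depend on sweep order).
#' @param resolution resolution parameter gamma; 1.0 is classic Newman
#'   modularity.
#' @return a `ppi_partition`: list with `membership` (named integer vector of
#'   0-based module labels, contiguous, ordered by decreasing module size with
#'   ties broken by smallest member name), `modularity` (Q at gamma = 1 of the
#'   returned assignment), `seed`, and `resolution`.
#' @examples
#' g <- igraph::make_graph(~ a - b, b - c, c - a, d - e, e - f, f - d)
#' p <- louvain_partition(g, seed = 1)
#' p$modularity  # 0.5
#' @export
louvain_partition <- function(graph, seed, resolution = 1.0) {
  stopifnot(inherits(graph, "igraph"))
  n <- igraph::vcount(graph)
  if (n == 0L) stop_fmt("louvain_partition: empty graph")
  if (igraph::ecount(graph) == 0L) stop_fmt("louvain_partition: graph has no edges")
  if (!is.numeric(resolution) || resolution <= 0) {
    stop_fmt("louvain_partition: 'resolution' must be positive")
  }
  a0 <- graph_arrays(graph)
  a <- a0
  node_map <- seq_len(n)
  q_prev <- q_of(a0$n, a0$i, a0$j, a0$w, a0$self, node_map, resolution)
  with_seed(seed, {
    repeat {
      comm <- louvain_one_level(a$n, a$i, a$j, a$w, a$self, resolution)
      node_map_new <- comm[node_map]
      q_new <- q_of(a0$n, a0$i, a0$j, a0$w, a0$self,
                    as.integer(factor(node_map_new)), resolution)
      if (q_new - q_prev < 1e-12) break
      q_prev <- q_new
      agg <- aggregate_level(a$n, a$i, a$j, a$w, a$self, comm)
      node_map <- agg$dense[node_map]   # orig node -> new super-node index
      a <- agg
    }
  })
  names(node_map) <- igraph::V(graph)$name %||% as.character(seq_len(n))
  membership <- canonical_labels(node_map)
  structure(
    list(membership = membership,
         modularity = modularity_q(graph, membership),
         seed = as.integer(seed),
         resolution = resolution),
    class = "ppi_partition")
}

# relabel communities 0..M-1 by decreasing size, ties by smallest member name
canonical_labels <- function(membership) {
  stopifnot(!is.null(names(membership)))
  groups <- split(names(membership), membership)
  sizes <- lengths(groups)
  mins <- vapply(groups, min, character(1))
  ord <- order(-sizes, mins)
  new_label <- integer(length(groups))
  new_label[ord] <- seq_along(groups) - 1L
  out <- new_label[match(membership, names(groups))]
  names(out) <- names(membership)
  out
}

#' Build a partition object from a known assignment
#'
#' Canonicalizes an arbitrary node -> label assignment (e.g. planted blocks)
#' into the same `ppi_partition` shape [louvain_partition()] returns.
#'
#' @param membership named vector of labels.
#' @param graph optional igraph; if supplied, modularity is computed.
#' @param seed integer recorded on the object (default `NA`).
#' @return a `ppi_partition`.
#' @export
as_partition <- function(membership, graph = NULL, seed = NA_integer_) {
  if (is.null(names(membership))) {
    stop_fmt("as_partition: 'membership' must be named by node")
  }
  m <- canonical_labels(membership)
  structure(list(membership = m,
                 modularity = if (is.null(graph)) NA_real_
                              else modularity_q(graph, m),
                 seed = as.integer(seed),
                 resolution = 1.0),
            class = "ppi_partition")
}

#' @export
print.ppi_partition <- function(x, ...) {
  cat(sprintf("<ppi_partition> %d nodes in %d modules, Q = %.4f (seed %s)\n",
              length(x$membership), length(unique(x$membership)),
              x$modularity, x$seed))
  invisible(x)
}

#' Module sizes of a partition
#'
#' @param partition a `ppi_partition`.
#' @return data.frame with columns `module` (label, ascending) and `size`;
#'   sizes sum to the node count.
#' @export
partition_summary <- function(partition) {
  stopifnot(inherits(partition, "ppi_partition"))
  tab <- table(partition$membership)
  data.frame(module = as.integer(names(tab)), size = as.integer(tab),
             row.names = NULL)
}

#' Members of each module
#'
#' @param partition a `ppi_partition`.
#' @return named list: label (as character) -> character vector of node names.
#' @export
module_members <- function(partition) {
  stopifnot(inherits(partition, "ppi_partition"))
  split(names(partition$membership), partition$membership)
}

#' Adjusted Rand Index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items; 1 for
#' identical partitions (up to relabeling), ~0 for independent ones.  Used to
#' score recovery of planted blocks.
#'
#' @param a,b label vectors; if both are named they are aligned by name.
#' @return the ARI, a number `<= 1`.
#' @export
adjusted_rand_index <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    if (!setequal(names(a), names(b))) {
      stop_fmt("adjusted_rand_index: name sets differ")
    }
    b <- b[names(a)]
  }
  if (length(a) != length(b)) stop_fmt("adjusted_rand_index: length mismatch")
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  nn <- choose(sum(tab), 2)
  expected <- ai * bj / nn
  denom <- (ai + bj) / 2 - expected
  if (denom == 0) return(1)               # both partitions trivial
  (nij - expected) / denom
}
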