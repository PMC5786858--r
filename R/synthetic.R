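#' Synthetic data with planted structure
#'
#' Generators that emulate the statistical shape of the real inputs at desk
#' scale: a sparse weighted interaction network with planted community
#' structure (stochastic block model), a disease gene set concentrated in a
#' few planted blocks at a multiple of the background rate, a symptom-gene
#' bipartite map concentrated in a subset of those blocks, and small target
#' sets overlapping the planted gene set.  All randomness flows from explicit
#' seeds; per-symptom seeds derive as `seed + index`.
#'
#' @name synthetic_data
NULL

#' Stochastic-block-model specification
#'
#' @param block_sizes integer vector of block sizes (all >= 1).
#' @param p_in within-block edge probability.
#' @param p_out between-block edge probability (`0 <= p_out <= p_in <= 1`).
#' @param edge_weight integer score given to every generated edge (default
#'   999, comfortably above the usual 700 confidence filter; the pipeline's
#'   statistics ignore weight magnitude beyond filtering).
#' @param seed integer seed.
#' @return object of class `sbm_spec`.
#' @export
sbm_spec <- function(block_sizes, p_in, p_out, edge_weight = 999L, seed = 1L) {
  if (!all(vapply(block_sizes, is_count, logical(1))) || any(block_sizes < 1)) {
    stop_fmt("sbm_spec: block sizes must be integers >= 1")
  }
  if (!is.numeric(p_in) || !is.numeric(p_out) ||
      p_out < 0 || p_in > 1 || p_out > p_in) {
    stop_fmt("sbm_spec: need 0 <= p_out <= p_in <= 1")
  }
  if (!is_count(edge_weight) || edge_weight < 1 || edge_weight > 1000) {
    stop_fmt("sbm_spec: edge_weight must be an integer in [1, 1000]")
  }
  structure(list(block_sizes = as.integer(block_sizes), p_in = p_in,
                 p_out = p_out, edge_weight = as.integer(edge_weight),
                 seed = as.integer(seed)),
            class = "sbm_spec")
}

#' Planted-gene-set specification
#'
#' @param enriched_blocks indices of the blocks carrying the planted signal.
#' @param q_in per-node inclusion probability inside enriched blocks.
#' @param q_out background inclusion probability elsewhere
#'   (`0 <= q_out < q_in <= 1`).
#' @param seed integer seed.
#' @return object of class `plant_spec`.
#' @export
plant_spec <- function(enriched_blocks, q_in, q_out, seed = 1L) {
  if (!is.numeric(q_in) || !is.numeric(q_out) ||
      q_out < 0 || q_in > 1 || q_out >= q_in) {
    stop_fmt("plant_spec: need 0 <= q_out < q_in <= 1")
  }
  if (!all(vapply(enriched_blocks, is_count, logical(1)))) {
    stop_fmt("plant_spec: enriched_blocks must be block indices")
  }
  structure(list(enriched_blocks = as.integer(enriched_blocks),
                 q_in = q_in, q_out = q_out, seed = as.integer(seed)),
            class = "plant_spec")
}

#' Generate a stochastic-block-model network
#'
#' Nodes are named `B<block>_N<index>`; every within-block pair is edged with
#' probability `p_in`, between-block pairs with `p_out`; all edges carry the
#' constant `edge_weight`.  Identical seeds give byte-identical edge lists.
#'
#' @param spec an [sbm_spec()].
#' @return list with `graph` (igraph; all nodes present, including isolated
#'   ones) and `assignment` (named integer vector node -> block index).
#' @export
generate_sbm <- function(spec) {
  stopifnot(inherits(spec, "sbm_spec"))
  sizes <- spec$block_sizes
  blocks <- rep(seq_along(sizes), sizes)
  n <- length(blocks)
  nodes <- sprintf("B%d_N%d", blocks,
                   unlist(lapply(sizes, seq_len), use.names = FALSE))
  same <- outer(blocks, blocks, "==")
  prob <- ifelse(same, spec$p_in, spec$p_out)
  ut <- which(upper.tri(prob), arr.ind = TRUE)
  keep <- with_seed(spec$seed, stats::runif(nrow(ut)) < prob[ut])
  el <- ut[keep, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = nodes[el[, 1L]], to = nodes[el[, 2L]],
               weight = spec$edge_weight, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE))
  assignment <- stats::setNames(blocks, nodes)
  list(graph = g, assignment = assignment)
}

#' Plant a gene set over the blocks of a network
#'
#' Each node joins the set independently: with probability `q_in` in enriched
#' blocks, `q_out` elsewhere.
#'
#' @param assignment named node -> block vector (from [generate_sbm()]).
#' @param spec a [plant_spec()].
#' @param name,source passed to [gene_set()].
#' @return a [gene_set()].
#' @export
plant_gene_set <- function(assignment, spec, name = "planted",
                           source = "disease") {
  stopifnot(inherits(spec, "plant_spec"))
  if (length(setdiff(spec$enriched_blocks, unique(assignment)))) {
    stop_fmt("plant_gene_set: enriched_blocks not all present in assignment")
  }
  rate <- ifelse(assignment %in% spec$enriched_blocks, spec$q_in, spec$q_out)
  hit <- with_seed(spec$seed, stats::runif(length(assignment)) < rate)
  gene_set(name, names(assignment)[hit], source = source)
}

#' Generate a symptom-gene bipartite map with planted structure
#'
#' Each symptom's gene set is planted independently via [plant_gene_set()]
#' with a per-symptom seed `spec$seed + index`.  Symptoms that draw an empty
#' gene set are dropped with a warning (a bipartite map may not contain
#' empty sets).
#'
#' @param assignment named node -> block vector.
#' @param symptoms character vector of symptom labels (>= 1).
#' @param spec a [plant_spec()].
#' @return a [bipartite_map()].
#' @export
generate_symptom_map <- function(assignment, symptoms, spec) {
  stopifnot(inherits(spec, "plant_spec"))
  if (!length(symptoms)) stop_fmt("generate_symptom_map: need >= 1 symptom")
  sets <- lapply(seq_along(symptoms), function(s) {
    sp <- spec
    sp$seed <- spec$seed + s
    plant_gene_set(assignment, sp, name = symptoms[[s]],
                   source = "symptom")$members
  })
  names(sets) <- symptoms
  empty <- lengths(sets) == 0L
  if (any(empty)) {
    warn_fmt("generate_symptom_map: dropped %d symptom(s) with empty gene sets",
             sum(empty))
    sets <- sets[!empty]
  }
  if (!length(sets)) stop_fmt("generate_symptom_map: all symptoms drew empty sets")
  bipartite_map(sets)
}

#' Generate a target set overlapping a planted gene set
#'
#' Samples `floor(overlap_fraction * |planted|)` members of the planted set
#' and adds `decoy_count` identifiers guaranteed absent from the planted set
#' (and from `avoid`, e.g. the graph's node names; colliding decoys are
#' resampled).
#'
#' @param planted_gene_set a [gene_set()].
#' @param overlap_fraction fraction of the planted set to include, in
#'   `[0, 1]`.
#' @param decoy_count number of decoy identifiers.
#' @param seed integer seed.
#' @param avoid character vector of identifiers decoys must not collide with.
#' @param name,source passed to [gene_set()].
#' @return a [gene_set()].
#' @export
generate_target_sets <- function(planted_gene_set, overlap_fraction,
                                 decoy_count = 0L, seed = 1L,
                                 avoid = character(), name = "targets",
                                 source = "target_drug") {
  stopifnot(inherits(planted_gene_set, "gene_set"))
  if (!is.numeric(overlap_fraction) || overlap_fraction < 0 ||
      overlap_fraction > 1) {
    stop_fmt("generate_target_sets: 'overlap_fraction' must be in [0, 1]")
  }
  if (!is_count(decoy_count)) {
    stop_fmt("generate_target_sets: 'decoy_count' must be a non-negative integer")
  }
  members <- planted_gene_set$members
  n_take <- floor(overlap_fraction * length(members))
  forbidden <- union(members, avoid)
  with_seed(seed, {
    base <- if (n_take > 0) sample(members, n_take) else character()
    decoys <- character()
    while (length(decoys) < decoy_count) {
      cand <- sprintf("DECOY_%06d",
                      sample.int(1e6L, decoy_count - length(decoys)))
      decoys <- unique(c(decoys, setdiff(cand, forbidden)))
    }
    gene_set(name, c(base, decoys), source = source)
  })
}
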