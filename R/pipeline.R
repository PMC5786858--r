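#' Pipeline driver: config validation and orchestrated run
#'
#' Runs the whole analysis behind one call: load (or simulate) the network,
#' partition it, enrich and select disease modules, optionally enrich the
#' symptom map and select syndrome modules, overlay target sets, run ORA per
#' disease module, and write the per-module report.  Configuration is a flat
#' `key: value` text file (a YAML-like dialect restricted to scalars; `#`
#' comments allowed).
#'
#' @name cli_pipeline
NULL

pipeline_defaults <- function() list(
  network = NULL,            # path to STRING-links file (xor sbm_blocks)
  score_threshold = 700,
  strict = TRUE,
  seed = NULL,               # mandatory
  resolution = 1.0,
  alpha = 0.01,
  rr_multiplier = 3.0,
  background = "covered_modules",
  disease_genes = NULL,      # path; in SBM mode NULL means "use planted set"
  symptom_map = NULL,        # path (two-column symptom \t gene)
  targets_ihd = NULL,
  targets_bs = NULL,
  targets_ps = NULL,
  gmt = NULL,
  out_dir = "dismod_out",
  # simulate-then-run scenario (used when 'network' is absent)
  sbm_blocks = NULL,         # e.g. "8x40" or "40,40,30"
  sbm_p_in = 0.25,
  sbm_p_out = 0.004,
  sbm_edge_weight = 999,
  plant_blocks = "1,2",
  q_in = 0.5,
  q_out = 0.05,
  symptoms = 7,
  symptom_blocks = "1"
)

parse_block_sizes <- function(x) {
  x <- trimws(as.character(x))
  if (grepl("^[0-9]+x[0-9]+$", x)) {
    p <- as.integer(strsplit(x, "x", fixed = TRUE)[[1L]])
    return(rep(p[2L], p[1L]))
  }
  as.integer(strsplit(x, ",", fixed = TRUE)[[1L]])
}

parse_int_list <- function(x) as.integer(strsplit(trimws(as.character(x)),
                                                  ",", fixed = TRUE)[[1L]])

coerce_value <- function(v) {
  v <- trimws(v)
  if (tolower(v) %in% c("true", "yes")) return(TRUE)
  if (tolower(v) %in% c("false", "no")) return(FALSE)
  if (grepl("^-?[0-9]+(\\.[0-9]+)?([eE][+-]?[0-9]+)?$", v)) return(as.numeric(v))
  v
}

#' Validate a pipeline configuration file
#'
#' Parses a flat `key: value` (or `key = value`) file, fills defaults, and
#' reports every violation found, not just the first.
#'
#' @param path config file path, or a named list of settings.
#' @param strict if `TRUE` (default) unknown keys are an error, otherwise a
#'   warning.
#' @return a normalized `pipeline_config` list.
#' @export
validate_config <- function(path, strict = TRUE) {
  cfg <- pipeline_defaults()
  if (is.list(path)) {
    user <- path
  } else {
    b <- read_body_lines(path)
    if (!length(b$lines)) stop_fmt("validate_config: '%s' is empty", path)
    m <- regmatches(b$lines,
                    regexec("^\\s*([A-Za-z0-9_]+)\\s*[:=]\\s*(.*?)\\s*$", b$lines))
    bad <- which(lengths(m) != 3L)
    if (length(bad)) {
      stop_fmt("validate_config: line %d is not 'key: value'", b$lineno[bad[1L]])
    }
    user <- stats::setNames(lapply(m, function(x) coerce_value(x[[3L]])),
                            vapply(m, `[[`, character(1), 2L))
  }
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown)) {
    msg <- sprintf("unknown key(s): %s", paste(unknown, collapse = ", "))
    if (strict) stop_fmt("validate_config: %s", msg) else warn_fmt("validate_config: %s", msg)
    user <- user[setdiff(names(user), unknown)]
  }
  cfg[names(user)] <- user

  problems <- character()
  add <- function(fmt, ...) problems <<- c(problems, sprintf(fmt, ...))
  if (is.null(cfg$seed) || !is_count(cfg$seed)) {
    add("'seed' is required and must be a non-negative integer")
  }
  if (!is.numeric(cfg$alpha) || cfg$alpha <= 0 || cfg$alpha > 1) {
    add("'alpha' must be in (0, 1], got %s", format(cfg$alpha))
  }
  if (!is.numeric(cfg$rr_multiplier) || cfg$rr_multiplier < 0) {
    add("'rr_multiplier' must be >= 0")
  }
  if (!is.numeric(cfg$score_threshold) || cfg$score_threshold < 0 ||
      cfg$score_threshold > 1000) {
    add("'score_threshold' must be in [0, 1000]")
  }
  if (!cfg$background %in% c("covered_modules", "whole_graph")) {
    add("'background' must be covered_modules or whole_graph")
  }
  if (is.null(cfg$network) && is.null(cfg$sbm_blocks)) {
    add("one of 'network' (file) or 'sbm_blocks' (simulation) is required")
  }
  for (key in c("network", "disease_genes", "symptom_map", "targets_ihd",
                "targets_bs", "targets_ps", "gmt")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]])) {
      add("'%s': file not found: %s", key, cfg[[key]])
    }
  }
  if (!is.null(cfg$network) && is.null(cfg$disease_genes)) {
    add("'disease_genes' is required when 'network' is a file")
  }
  if (length(problems)) {
    stop_fmt("validate_config: %d problem(s):\n- %s",
             length(problems), paste(problems, collapse = "\n- "))
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Stages: graph (load or simulate), partition, enrichment + selection,
#' target overlays, per-module ORA, report.  Counts are logged at each stage
#' (nodes, edges, modules, potential modules, covered universe, K, background
#' proportion).  On any stage error the partial outputs are removed and the
#' error names the failing stage.  Two runs with the same config and seed
#' produce byte-identical outputs.
#'
#' @param config a `pipeline_config` (from [validate_config()]), a config
#'   file path, or a named list of settings.
#' @param stop_after run only through this stage: `"partition"`, `"enrich"`,
#'   `"ora"` or `"report"` (default, the full run).
#' @return invisibly, a list with the partition, enrichment tables,
#'   selections, report rows, counts, and the paths written.
#' @export
run_pipeline <- function(config, stop_after = c("report", "partition",
                                                "enrich", "ora")) {
  stop_after <- match.arg(stop_after)
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  written <- character()
  emit <- function(file) {
    path <- file.path(out_dir, file)
    written <<- c(written, path)
    path
  }
  stage <- "setup"
  result <- tryCatch({
    ## ---- stage: graph ----
    stage <- "graph_io"
    truth <- NULL
    sim_mode <- is.null(config$network)
    if (sim_mode) {
      sspec <- sbm_spec(parse_block_sizes(config$sbm_blocks),
                        config$sbm_p_in, config$sbm_p_out,
                        config$sbm_edge_weight, seed = config$seed)
      sim <- generate_sbm(sspec)
      graph <- sim$graph
      truth <- sim$assignment
      write_string_links(graph, emit("network.tsv"))
      writeLines(paste(names(truth), truth, sep = "\t"), emit("truth.tsv"))
    } else {
      graph <- load_string_links(config$network,
                                 min_score = config$score_threshold,
                                 strict = config$strict)
    }
    message(sprintf("[graph] %d nodes, %d edges",
                    igraph::vcount(graph), igraph::ecount(graph)))

    ## ---- stage: disease genes ----
    stage <- "gene_curation"
    if (!is.null(config$disease_genes)) {
      dsets <- load_gene_sets(config$disease_genes, source = "disease")
      disease_genes <- if (length(dsets) > 1L) merge_sources(dsets)$union
                       else dsets[[1L]]
    } else {
      pspec <- plant_spec(parse_int_list(config$plant_blocks),
                          config$q_in, config$q_out,
                          seed = config$seed + 1000L)
      disease_genes <- plant_gene_set(truth, pspec, name = "disease")
      write_gene_sets(disease_genes, emit("disease_genes.tsv"))
    }
    message(sprintf("[genes] %d disease genes", length(disease_genes$members)))

    ## ---- stage: partition ----
    stage <- "community_detection"
    partition <- louvain_partition(graph, seed = config$seed,
                                   resolution = config$resolution)
    writeLines(c("node\tmodule",
                 paste(names(partition$membership), partition$membership,
                       sep = "\t")),
               emit("partition.tsv"))
    summ <- partition_summary(partition)
    writeLines(c("module\tsize", paste(summ$module, summ$size, sep = "\t")),
               emit("partition_summary.tsv"))
    message(sprintf("[partition] %d modules, Q = %.4f", nrow(summ),
                    partition$modularity))
    if (stop_after == "partition") {
      return(invisible(list(config = config, partition = partition,
                            paths = written)))
    }

    ## ---- stage: enrichment ----
    stage <- "set_enrichment"
    pot <- select_potential_modules(partition, disease_genes)
    bg <- if (config$background == "whole_graph") {
      background(igraph::V(graph)$name, policy = "whole_graph")
    } else {
      background(pot$universe, policy = "covered_modules")
    }
    disease_records <- enrich_modules(partition, disease_genes, bg,
                                      modules = pot$modules,
                                      alpha = config$alpha,
                                      rr_multiplier = config$rr_multiplier)
    write_enrichment_tsv(disease_records, emit("disease_enrichment.tsv"))
    disease_sel <- select_disease_modules(disease_records,
                                          alpha = config$alpha,
                                          rr_multiplier = config$rr_multiplier)
    message(sprintf(
      "[enrich] %d potential modules; universe N = %d; K = %d; background = %.4f; %d disease modules",
      length(pot$modules), length(bg$universe), disease_records$K[1] %||% 0L,
      (disease_records$background_proportion[1] %||% NA_real_),
      nrow(disease_sel)))

    symptom_records <- NULL
    syndrome_sel <- NULL
    if (!is.null(config$symptom_map) || sim_mode) {
      if (!is.null(config$symptom_map)) {
        smap <- load_bipartite(config$symptom_map)
      } else {
        sp <- plant_spec(parse_int_list(config$symptom_blocks),
                         config$q_in, config$q_out,
                         seed = config$seed + 2000L)
        smap <- generate_symptom_map(truth,
                                     sprintf("symptom_%d",
                                             seq_len(config$symptoms)), sp)
        write_bipartite(smap, emit("symptom_map.tsv"))
      }
      symptom_genes <- flatten_genes(smap)
      symptom_records <- enrich_modules(partition, symptom_genes, bg,
                                        modules = pot$modules,
                                        alpha = config$alpha,
                                        rr_multiplier = config$rr_multiplier)
      write_enrichment_tsv(symptom_records, emit("symptom_enrichment.tsv"))
      syndrome_sel <- select_syndrome_modules(symptom_records, disease_sel,
                                              alpha = config$alpha)
      message(sprintf("[enrich] %d symptom genes; %d syndrome modules",
                      length(symptom_genes), nrow(syndrome_sel)))
    }
    if (stop_after == "enrich") {
      return(invisible(list(config = config, partition = partition,
                            disease_records = disease_records,
                            symptom_records = symptom_records,
                            selections = list(disease = disease_sel,
                                              syndrome = syndrome_sel),
                            background = bg, paths = written)))
    }

    ## ---- stage: ORA ----
    stage <- "annotation_ora"
    ora_tables <- list()
    if (!is.null(config$gmt) && nrow(disease_sel)) {
      collection <- load_gmt(config$gmt)
      mm <- module_members(partition)
      for (lab in disease_sel$module) {
        res <- ora(mm[[as.character(lab)]], collection, bg,
                   alpha = config$alpha)
        ora_tables[[as.character(lab)]] <- res
        path <- emit(sprintf("ora_module_%d.tsv", lab))
        header <- paste(names(res), collapse = "\t")
        body <- vapply(seq_len(nrow(res)), function(r) paste(
          res$term[r], res$k[r], res$n[r], res$K[r], res$N[r],
          fmt_p(res$p_value[r]), fmt_p(res$cpv[r]), res$significant[r],
          sep = "\t"), character(1))
        writeLines(c(header, body), path)
      }
      message(sprintf("[ora] wrote %d module table(s)", length(ora_tables)))
    }
    if (stop_after == "ora") {
      return(invisible(list(config = config, partition = partition,
                            disease_records = disease_records,
                            symptom_records = symptom_records,
                            selections = list(disease = disease_sel,
                                              syndrome = syndrome_sel),
                            ora = ora_tables, background = bg,
                            paths = written)))
    }

    ## ---- stage: report ----
    stage <- "module_report"
    overlays <- list()
    load_targets <- function(path, source) {
      sets <- load_gene_sets(path, source = source)
      unique(unlist(lapply(sets, `[[`, "members"), use.names = FALSE))
    }
    if (!is.null(config$targets_ihd)) {
      overlays$ihd <- overlay_targets(partition,
                                      load_targets(config$targets_ihd,
                                                   "target_drug"))
    }
    if (!is.null(config$targets_bs)) {
      overlays$formula_bs <- overlay_targets(
        partition, load_targets(config$targets_bs, "target_formula_BS"))
    }
    if (!is.null(config$targets_ps)) {
      overlays$formula_ps <- overlay_targets(
        partition, load_targets(config$targets_ps, "target_formula_PS"))
    }
    report <- NULL
    if (nrow(disease_sel)) {
      report <- build_report(disease_records, symptom_records, overlays,
                             list(disease = disease_sel,
                                  syndrome = syndrome_sel))
      write_report(report, emit("report.tsv"), format = "tsv")
      write_report(report, emit("report.json"), format = "json")
      message(sprintf("[report] %d row(s), %d syndrome-flagged",
                      nrow(report), sum(report$is_syndrome_module)))
    } else {
      message("[report] no disease modules selected; report not written")
    }
    invisible(list(config = config, partition = partition,
                   disease_records = disease_records,
                   symptom_records = symptom_records,
                   selections = list(disease = disease_sel,
                                     syndrome = syndrome_sel),
                   ora = ora_tables, overlays = overlays,
                   report = report, background = bg, paths = written))
  }, error = function(e) {
    unlink(written)
    stop_fmt("run_pipeline: stage '%s' failed: %s", stage, conditionMessage(e))
  })
  result
}
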