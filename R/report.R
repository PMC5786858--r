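#' Per-module summary report with target overlays
#'
#' The headline deliverable of a run: one row per disease module with the
#' disease and symptom enrichment counts and p-values, plus overlay counts of
#' known drug targets and herbal-formula targets, mirroring the layout of a
#' per-module validation table.
#'
#' @name module_report
NULL

#' Count target genes inside modules
#'
#' @param partition a `ppi_partition`.
#' @param targets a [gene_set()] or character vector of target genes
#'   (deduplicated upstream, so the counts are duplication-invariant).
#' @param modules integer labels to count in; `NULL` = all modules.
#' @return named integer vector: label -> `|module members  targets|`.
#' @export
overlay_targets <- function(partition, targets, modules = NULL) {
  stopifnot(inherits(partition, "ppi_partition"))
  tg <- as_members(targets, "targets")
  mm <- module_members(partition)
  labels <- as.integer(names(mm))
  if (is.null(modules)) modules <- labels
  unknown <- setdiff(modules, labels)
  if (length(unknown)) {
    stop_fmt("overlay_targets: unknown module label(s): %s",
             paste(unknown, collapse = ", "))
  }
  counts <- vapply(mm[as.character(modules)],
                   function(m) length(intersect(m, tg)), integer(1))
  names(counts) <- as.character(modules)
  counts
}

#' Assemble the per-module report
#'
#' @param disease_records `module_enrichment` records for the disease gene
#'   set (must cover every selected disease module).
#' @param symptom_records `module_enrichment` records for the symptom gene
#'   union computed against the same background, or `NULL` if no symptom data
#'   was supplied (symptom columns become `NA`).
#' @param target_overlays named list of overlay count vectors from
#'   [overlay_targets()]; recognized names are `ihd`, `formula_bs`,
#'   `formula_ps` (missing entries count 0).
#' @param selections list with `disease` and `syndrome` module label vectors
#'   (e.g. from [select_disease_modules()] / [select_syndrome_modules()]).
#' @return data.frame of class `module_report`, one row per disease module,
#'   sorted by ascending disease p-value.
#' @export
build_report <- function(disease_records, symptom_records = NULL,
                         target_overlays = list(), selections) {
  stopifnot(is.data.frame(disease_records), is.list(selections))
  disease <- as.integer(if (is.data.frame(selections$disease))
    selections$disease$module else selections$disease %||% integer())
  syndrome <- as.integer(if (is.data.frame(selections$syndrome))
    selections$syndrome$module else selections$syndrome %||% integer())
  if (length(setdiff(syndrome, disease))) {
    stop_fmt("build_report: syndrome modules must be a subset of disease modules")
  }
  if (length(setdiff(disease, disease_records$module))) {
    stop_fmt("build_report: disease record(s) missing for module(s): %s",
             paste(setdiff(disease, disease_records$module), collapse = ", "))
  }
  if (!is.null(symptom_records) &&
      length(setdiff(disease, symptom_records$module))) {
    stop_fmt("build_report: symptom record(s) missing for module(s): %s",
             paste(setdiff(disease, symptom_records$module), collapse = ", "))
  }
  di <- match(disease, disease_records$module)
  ov <- function(name) {
    v <- target_overlays[[name]]
    if (is.null(v)) return(rep(0L, length(disease)))
    out <- v[as.character(disease)]
    out[is.na(out)] <- 0L
    as.integer(out)
  }
  if (!is.null(symptom_records)) {
    si <- match(disease, symptom_records$module)
    sk <- symptom_records$k[si]; sn <- symptom_records$n[si]
    sp <- symptom_records$p_value[si]
  } else {
    sk <- sn <- rep(NA_integer_, length(disease))
    sp <- rep(NA_real_, length(disease))
  }
  rows <- data.frame(
    module = disease,
    disease_k = disease_records$k[di],
    disease_n = disease_records$n[di],
    disease_p = disease_records$p_value[di],
    symptom_k = sk, symptom_n = sn, symptom_p = sp,
    n_ihd_targets = ov("ihd"),
    n_bs_formula_targets = ov("formula_bs"),
    n_ps_formula_targets = ov("formula_ps"),
    is_disease_module = TRUE,
    is_syndrome_module = disease %in% syndrome,
    row.names = NULL)
  rows <- rows[order(rows$disease_p, rows$module), , drop = FALSE]
  rownames(rows) <- NULL
  class(rows) <- c("module_report", "data.frame")
  rows
}

fmt_p <- function(p) ifelse(is.na(p), "NA", formatC(p, format = "e", digits = 2))

#' Write the report to disk
#'
#' Deterministic, byte-stable output: p-values in scientific notation with 3
#' significant digits in the TSV; the JSON carries unrounded values and
#' round-trips to equal rows.
#'
#' @param rows a `module_report` data.frame (non-empty).
#' @param path output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(rows, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(rows))
  if (!nrow(rows)) stop_fmt("write_report: empty report")
  if (format == "json") {
    jsonlite::write_json(as.data.frame(rows), path,
                         auto_unbox = FALSE, digits = NA, pretty = TRUE)
    return(invisible(path))
  }
  header <- paste(names(rows), collapse = "\t")
  body <- vapply(seq_len(nrow(rows)), function(r) {
    vals <- vapply(names(rows), function(cn) {
      v <- rows[[cn]][r]
      if (cn %in% c("disease_p", "symptom_p")) fmt_p(v)
      else if (is.logical(v)) as.character(v)
      else if (is.na(v)) "NA"
      else as.character(v)
    }, character(1))
    paste(vals, collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read back a JSON report
#' @param path path written by [write_report()] with `format = "json"`.
#' @return a `module_report` data.frame.
#' @export
read_report_json <- function(path) {
  rows <- jsonlite::fromJSON(path)
  class(rows) <- c("module_report", "data.frame")
  rows
}

#' Write an enrichment table as TSV (deterministic formatting)
#' @param records a `module_enrichment` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_enrichment_tsv <- function(records, path) {
  stopifnot(is.data.frame(records))
  header <- paste(names(records), collapse = "\t")
  body <- vapply(seq_len(nrow(records)), function(r) {
    vals <- vapply(names(records), function(cn) {
      v <- records[[cn]][r]
      if (cn == "p_value" || cn == "cpv") fmt_p(v)
      else if (cn %in% c("proportion", "background_proportion"))
        formatC(v, format = "f", digits = 4)
      else as.character(v)
    }, character(1))
    paste(vals, collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}
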