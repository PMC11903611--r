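#' Run the full mRNA-protein concordance pipeline
#'
#' Executes ingestion, filtering, discretization, pairing, concordance
#' summarization, independence testing and cross-platform validation in
#' order, writing all result files and a machine-parseable audit trail of
#' record counts at every filter step.
#'
#' @param config either a list or a path to a YAML file with elements:
#'   \describe{
#'     \item{paths}{named list of input files: `protein`, `rna` (required),
#'       `ms`, `external_rna` (optional; missing tables degrade gracefully
#'       with validation rows reported as missing).}
#'     \item{out_dir}{output directory; created if needed. `NULL` skips all
#'       file output.}
#'     \item{thresholds}{named list passed to [validation_thresholds()].}
#'     \item{keep_cell_types}{cell types to retain, default glomerular and
#'       tubular.}
#'     \item{join_by}{pairing key, `"gene_id"` (default) or `"gene_name"`.}
#'     \item{strict}{if `TRUE`, recoverable data problems become errors.}
#'   }
#' @return invisibly, a list with `summary` (a `concordance_summary`),
#'   `pairs`, `contingency`, `tertiles`, `audit` (tibble of stage/metric/
#'   value rows) and `files` (paths written).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config), !is.null(config$paths))
  paths <- config$paths
  strict <- isTRUE(config$strict)
  keep <- config$keep_cell_types %||%
    c("cells in glomeruli", "cells in tubules")
  join_by <- config$join_by %||% "gene_id"
  thresholds <- do.call(validation_thresholds,
                        config$thresholds %||% list())
  audit <- list()
  log_step <- function(stage, metric, value) {
    audit[[length(audit) + 1L]] <<- audit_record(stage, metric, value)
  }

  # -- ingest IHC protein table ------------------------------------------
  prot <- withCallingHandlers(
    read_protein_table(paths$protein, strict = strict),
    warning = function(w) invokeRestart("muffleWarning")
  )
  pa <- attr(prot, "audit")
  log_step("ingest_protein", "rows_in", pa$rows_in)
  log_step("ingest_protein", "dropped_tissue", pa$dropped_tissue)
  log_step("ingest_protein", "errored", pa$errored)
  log_step("ingest_protein", "deduplicated", pa$deduplicated)
  log_step("ingest_protein", "kept", pa$kept)

  # -- reliability and cell-type filters ---------------------------------
  reliable <- filter_reliability(prot)
  log_step("filter_reliability", "dropped_uncertain",
           attr(reliable, "n_removed"))
  log_step("filter_reliability", "kept", nrow(reliable))
  buckets <- select_cell_types(reliable, keep = keep)
  log_step("select_cell_types", "dropped_other_cell_types",
           attr(buckets, "n_dropped"))
  for (comp in names(buckets)) {
    log_step("select_cell_types", paste0("kept_", comp),
             nrow(buckets[[comp]]))
  }

  # -- ingest and discretize transcripts ---------------------------------
  rna <- read_quant_table(paths$rna, "hpa_rna_consensus", strict = strict)
  log_step("ingest_rna", "rows_in", attr(rna, "audit")$rows_in)
  rna <- rna[rna$tissue == "kidney", , drop = FALSE]
  log_step("ingest_rna", "kidney_rows", nrow(rna))
  tert <- compute_tertiles(rna)
  log_step("tertiles", "n_positive", tert$n_positive)
  rna$rna_category <- categorize_transcript(rna$ntpm, tert)

  # -- pair and tabulate -------------------------------------------------
  pairs <- pair_records(rna, buckets, by = join_by, strict = strict)
  unmatched <- attr(pairs, "unmatched")
  contingency <- list()
  concord <- list()
  chi <- list()
  for (comp in names(pairs)) {
    log_step("pair", paste0("paired_", comp), nrow(pairs[[comp]]))
    log_step("pair", paste0("transcript_only_", comp),
             unmatched[[comp]]$transcript_only)
    log_step("pair", paste0("protein_only_", comp),
             unmatched[[comp]]$protein_only)
    contingency[[comp]] <- build_contingency(pairs[[comp]])
    concord[[comp]] <- summarize_concordance(contingency[[comp]])
    chi[[comp]] <- tryCatch(
      chi_square_independence(contingency[[comp]]),
      error = function(e) {
        warning("independence test skipped for ", sQuote(comp), ": ",
                conditionMessage(e), call. = FALSE)
        NULL
      }
    )
  }

  # -- cross-platform validation -----------------------------------------
  ms <- if (!is.null(paths$ms)) {
    read_quant_table(paths$ms, "compartment_ms",
                     col_map = config$ms_col_map, strict = strict)
  }
  ext <- if (!is.null(paths$external_rna)) {
    read_quant_table(paths$external_rna, "compartment_rna",
                     col_map = config$external_rna_col_map, strict = strict)
  }
  protein_val <- lapply(pairs, validate_protein_nulls, ms = ms,
                        thresholds = thresholds)
  rna_val <- lapply(pairs, validate_rna_nulls, ext = ext,
                    thresholds = thresholds)

  summary <- assemble_summary(
    concord, protein_val, rna_val, chi = chi, thresholds = thresholds,
    diagnostics = unmatched
  )
  summary$tertiles <- unclass(tert)

  # -- write outputs ------------------------------------------------------
  files <- character(0)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    out <- function(name) file.path(config$out_dir, name)
    for (comp in names(pairs)) {
      emit_pair_table(pairs[[comp]], out(sprintf("pairs_%s.tsv", comp)))
      cm <- tibble::as_tibble(unclass(contingency[[comp]]),
                              rownames = "rna_category")
      readr::write_tsv(cm, out(sprintf("contingency_%s.tsv", comp)))
      files <- c(files, out(sprintf("pairs_%s.tsv", comp)),
                 out(sprintf("contingency_%s.tsv", comp)))
    }
    write_summary(summary, out("summary.tsv"), format = "tsv")
    write_summary(summary, out("summary.json"), format = "json")
    files <- c(files, out("summary.tsv"), out("summary.json"))
    files <- c(files, write_validated_genes(protein_val, rna_val,
                                            config$out_dir))
    audit_tab <- dplyr::bind_rows(audit)
    readr::write_tsv(audit_tab, out("run_log.tsv"))
    render_report(summary, out("report.md"), audit = audit_tab)
    snapshot <- config
    snapshot$thresholds <- unclass(thresholds)
    yaml::write_yaml(snapshot, out("config_snapshot.yaml"))
    files <- c(files, out("run_log.tsv"), out("report.md"),
               out("config_snapshot.yaml"))
  }

  invisible(list(
    summary = summary, pairs = pairs, contingency = contingency,
    tertiles = tert, audit = dplyr::bind_rows(audit), files = files
  ))
}

#' Render a human-readable concordance report
#'
#' Markdown report with the per-compartment count table (counts with
#' percentages of the pair total), the chi-square line, the thresholds
#' used, and the filter-step audit trail. Counts unavailable because a
#' validation table was missing are rendered as `missing`, not `0`.
#'
#' @param summary a `concordance_summary`.
#' @param path output file path.
#' @param audit optional audit tibble (`stage`, `metric`, `value`).
#' @return `path`, invisibly.
#' @export
render_report <- function(summary, path, audit = NULL) {
  stopifnot(inherits(summary, "concordance_summary"))
  comps <- names(summary$compartments)
  lines <- c("# Kidney mRNA-protein concordance report", "")
  header <- paste0("| Measure | ", paste(comps, collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", length(comps) + 1L), collapse = "|"),
                "|")
  lines <- c(lines, header, sep)
  for (m in names(.summary_measures)) {
    cells <- vapply(comps, function(comp) {
      cc <- summary$compartments[[comp]]
      n <- cc$counts[[m]]
      if (m == "total") format(as.integer(n))
      else format_count_pct(n, cc$counts$total)
    }, character(1))
    lines <- c(lines, paste0("| ", .summary_measures[[m]], " | ",
                             paste(cells, collapse = " | "), " |"))
  }
  lines <- c(lines, "")
  for (comp in comps) {
    cs <- summary$compartments[[comp]]$chi_square
    lines <- c(lines, if (is.null(cs)) {
      sprintf("- %s: independence test not available", comp)
    } else {
      sprintf(
        "- %s: chi-square X2 = %.4f, df = %d, p = %.3g (%s)%s",
        comp, cs$statistic, cs$degrees_of_freedom, cs$p_value, cs$table,
        if (cs$validity_warning) "; expected count < 5 present" else ""
      )
    })
  }
  thr <- summary$thresholds
  lines <- c(lines, "", "## Thresholds",
             sprintf("- mRNA detection: nTPM > %g (strict: nTPM >= %g)",
                     thr$ntpm_detect, thr$ntpm_strict),
             sprintf("- MS evidence: mean spectral count >= %g",
                     thr$spectral_min),
             sprintf("- external RNA evidence: TPM > %g (strict: TPM >= %g)",
                     thr$tpm_detect, thr$tpm_strict))
  if (!is.null(audit)) {
    lines <- c(lines, "", "## Filter audit trail", "",
               "| Stage | Metric | Value |", "|---|---|---|",
               sprintf("| %s | %s | %g |", audit$stage, audit$metric,
                       audit$value))
  }
  writeLines(lines, path)
  invisible(path)
}
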