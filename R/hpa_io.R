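#' Read an IHC protein-expression table (HPA normal-tissue dialect)
#'
#' Reads a tab-separated table with the columns `Gene`, `Gene name`,
#' `Tissue`, `Cell type`, `Level`, `Reliability` (the Human Protein Atlas
#' `normal_tissue.tsv` layout), keeps the rows for the requested tissue
#' (case-insensitive) and returns typed, normalized protein records.
#'
#' Level and reliability strings are case-folded and whitespace-trimmed
#' before matching. Rows whose level or reliability cannot be parsed are
#' skipped with a warning (an error in strict mode). Duplicate
#' `(gene_id, tissue, cell_type)` rows are collapsed to the highest ordinal
#' level with a warning.
#'
#' @param path path to a TSV file with a header row.
#' @param dialect input dialect; only `"hpa_normal_tissue"` is defined.
#' @param tissue tissue to retain (case-insensitive); default `"kidney"`.
#' @param strict if `TRUE`, unparseable rows and duplicate keys are errors.
#' @return tibble with columns `gene_id`, `gene_name`, `tissue`,
#'   `cell_type`, `level` (ordered factor), `reliability`; attribute
#'   `audit` records rows in / kept / dropped-by-tissue / errored /
#'   deduplicated.
#' @export
read_protein_table <- function(path, dialect = "hpa_normal_tissue",
                               tissue = "kidney", strict = FALSE) {
  dialect <- match.arg(dialect, "hpa_normal_tissue")
  raw <- .read_tsv_checked(path, required = c(
    "Gene", "Gene name", "Tissue", "Cell type", "Level", "Reliability"
  ))
  n_in <- nrow(raw)

  in_tissue <- .norm_key(raw$Tissue) == .norm_key(tissue)
  n_other_tissue <- sum(!in_tissue)
  raw <- raw[in_tissue, , drop = FALSE]

  level_key <- .norm_key(raw$Level)
  rel_key <- .norm_key(raw$Reliability)
  ok <- level_key %in% names(.level_lookup) &
    rel_key %in% names(.reliability_lookup)
  n_err <- sum(!ok)
  if (n_err > 0L) {
    bad <- unique(c(
      raw$Level[!level_key %in% names(.level_lookup)],
      raw$Reliability[!rel_key %in% names(.reliability_lookup)]
    ))
    msg <- sprintf("%d row(s) with unparseable level/reliability (%s)",
                   n_err, paste(sQuote(bad), collapse = ", "))
    if (strict) stop(msg, call. = FALSE)
    warning(msg, ", skipped", call. = FALSE)
  }
  raw <- raw[ok, , drop = FALSE]

  out <- tibble::tibble(
    gene_id = raw$Gene,
    gene_name = raw$`Gene name`,
    tissue = .norm_key(raw$Tissue),
    cell_type = .norm_key(raw$`Cell type`),
    level = normalize_ihc_level(raw$Level),
    reliability = normalize_reliability(raw$Reliability)
  )

  dup_key <- paste(out$gene_id, out$tissue, out$cell_type, sep = "\r")
  n_dup <- sum(duplicated(dup_key))
  if (n_dup > 0L) {
    if (strict) {
      stop(n_dup, " duplicate (gene, tissue, cell type) row(s), e.g. ",
           out$gene_id[duplicated(dup_key)][1L], call. = FALSE)
    }
    warning(n_dup, " duplicate (gene, tissue, cell type) row(s); ",
            "keeping the highest ordinal level", call. = FALSE)
    ord <- order(dup_key, -as.integer(out$level))
    out <- out[ord, , drop = FALSE]
    out <- out[!duplicated(paste(out$gene_id, out$tissue, out$cell_type,
                                 sep = "\r")), , drop = FALSE]
  }

  attr(out, "audit") <- list(
    rows_in = n_in, kept = nrow(out), dropped_tissue = n_other_tissue,
    errored = n_err, deduplicated = n_dup
  )
  out
}

# dialect -> default column mapping and output schema for quant tables
.quant_dialects <- list(
  hpa_rna_consensus = list(
    cols = c(gene_id = "Gene", gene_name = "Gene name", tissue = "Tissue",
             value = "nTPM"),
    value_name = "ntpm", key = c("gene_id", "tissue")
  ),
  compartment_ms = list(
    cols = c(gene_name = "gene_name", compartment = "compartment",
             value = "mean_spectral_count"),
    value_name = "mean_spectral_count", key = c("gene_name", "compartment")
  ),
  compartment_rna = list(
    cols = c(gene_name = "gene_name", compartment = "compartment",
             value = "tpm"),
    value_name = "tpm", key = c("gene_name", "compartment")
  )
)

#' Read a quantitative expression table
#'
#' Reads one of three TSV dialects into typed records: the HPA consensus
#' RNA layout (`Gene`, `Gene name`, `Tissue`, `nTPM`), a compartment-level
#' mass-spectrometry table (gene, compartment, mean spectral count), or a
#' compartment-level external RNA-seq table (gene, compartment, TPM). For
#' the MS and external-RNA dialects the physical column names are
#' configurable through `col_map`.
#'
#' Negative values are rejected with the offending row number. Duplicate
#' keys are collapsed to their arithmetic mean with a warning (an error in
#' strict mode).
#'
#' @param path path to a TSV file with a header row.
#' @param dialect one of `"hpa_rna_consensus"`, `"compartment_ms"`,
#'   `"compartment_rna"`.
#' @param col_map optional named character vector overriding the physical
#'   column names; logical names are `gene_id`/`gene_name`, `tissue` or
#'   `compartment`, and `value`.
#' @param strict if `TRUE`, duplicate keys are an error.
#' @return tibble of typed records; the value column is `ntpm`,
#'   `mean_spectral_count` or `tpm` by dialect. Attribute `audit` records
#'   rows in / kept / deduplicated.
#' @export
read_quant_table <- function(path, dialect, col_map = NULL, strict = FALSE) {
  dialect <- match.arg(dialect, names(.quant_dialects))
  spec <- .quant_dialects[[dialect]]
  cols <- spec$cols
  if (!is.null(col_map)) {
    bad <- setdiff(names(col_map), names(cols))
    if (length(bad) > 0L) {
      stop("unknown col_map field(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    cols[names(col_map)] <- col_map
  }
  raw <- .read_tsv_checked(path, required = unname(cols))
  n_in <- nrow(raw)

  val <- suppressWarnings(as.numeric(raw[[cols[["value"]]]]))
  if (anyNA(val) && !all(is.na(raw[[cols[["value"]]]]))) {
    bad_rows <- which(is.na(val) & !is.na(raw[[cols[["value"]]]]))
    stop("non-numeric value(s) in column ", sQuote(cols[["value"]]),
         " at data row(s) ", paste(utils::head(bad_rows, 5), collapse = ", "),
         call. = FALSE)
  }
  if (any(val < 0, na.rm = TRUE)) {
    stop("negative value(s) in column ", sQuote(cols[["value"]]),
         " at data row(s) ",
         paste(utils::head(which(val < 0), 5), collapse = ", "),
         call. = FALSE)
  }

  out <- tibble::tibble(.rows = n_in)
  for (logical_name in setdiff(names(cols), "value")) {
    out[[logical_name]] <- raw[[cols[[logical_name]]]]
  }
  if ("tissue" %in% names(out)) out$tissue <- .norm_key(out$tissue)
  if ("compartment" %in% names(out)) {
    out$compartment <- .norm_key(out$compartment)
  }
  out[[spec$value_name]] <- val

  key <- do.call(paste, c(out[spec$key], sep = "\r"))
  n_dup <- sum(duplicated(key))
  if (n_dup > 0L) {
    if (strict) {
      stop(n_dup, " duplicate key(s) in ", dialect, " table, e.g. ",
           gsub("\r", " / ", key[duplicated(key)][1L]), call. = FALSE)
    }
    warning(n_dup, " duplicate key(s) in ", dialect,
            " table; keeping arithmetic means", call. = FALSE)
    means <- tapply(out[[spec$value_name]], key, mean)
    first <- !duplicated(key)
    out <- out[first, , drop = FALSE]
    out[[spec$value_name]] <- as.numeric(means[key[first]])
  }

  attr(out, "audit") <- list(rows_in = n_in, kept = nrow(out),
                             deduplicated = n_dup)
  out
}

# internal: strict TSV reader with schema check
.read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, show_col_types = FALSE)
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0L) {
    stop("missing required column(s): ",
         paste(sQuote(missing), collapse = ", "), " in ", path,
         call. = FALSE)
  }
  raw
}

# the fixed row order of the per-compartment summary table
.summary_measures <- c(
  total = "Number of reliable paired mRNA-protein expression measurements",
  concordant = "Pairs with concordant abundance levels",
  discordant = "Pairs with discordant abundance levels",
  protein_null_rna_detected =
    "Pairs with no IHC signal but detected mRNA (nTPM > 0)",
  protein_null_ntpm_strict =
    "Pairs with no IHC signal but detected mRNA (nTPM >= 1)",
  protein_null_ms_validated =
    "Pairs with no IHC signal, detected mRNA, and compartment MS evidence (mean spectral count >= 1)",
  rna_null_protein_detected =
    "Pairs with no detectable mRNA but an IHC signal",
  rna_null_ext_detected =
    "Pairs with no detectable mRNA, an IHC signal, and external compartment RNA-seq evidence (TPM > 0)",
  rna_null_ext_strict =
    "Pairs with no detectable mRNA, an IHC signal, and external compartment RNA-seq evidence (TPM >= 1)"
)

#' Write a concordance summary to TSV or JSON
#'
#' The TSV rendering is the human-readable count table: one row per named
#' measure, one column per compartment, cells formatted `"N (P%)"` with the
#' compartment pair total as denominator. The JSON rendering is a lossless
#' machine twin ([read_summary_json()] restores a structurally equal
#' object).
#'
#' @param summary a `concordance_summary` from [assemble_summary()].
#' @param path output file path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summary, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(summary, "concordance_summary"))
  totals <- vapply(summary$compartments, function(x) x$counts[["total"]],
                   numeric(1))
  if (length(totals) == 0L || any(is.na(totals)) || any(totals <= 0)) {
    stop("refusing to serialize an empty summary (zero pair total)",
         call. = FALSE)
  }
  if (format == "json") {
    jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE,
                         digits = NA, null = "null", na = "null",
                         pretty = TRUE)
    return(invisible(path))
  }
  tab <- tibble::tibble(measure = unname(.summary_measures))
  for (comp in names(summary$compartments)) {
    cc <- summary$compartments[[comp]]
    cells <- vapply(names(.summary_measures), function(m) {
      n <- cc$counts[[m]]
      if (m == "total") {
        format(as.integer(n))
      } else if (is.na(n)) {
        "missing"
      } else {
        format_count_pct(n, cc$counts[["total"]])
      }
    }, character(1))
    tab[[comp]] <- unname(cells)
  }
  readr::write_tsv(tab, path)
  invisible(path)
}

#' Read back a JSON concordance summary
#'
#' @param path path written by [write_summary()] with `format = "json"`.
#' @return a `concordance_summary` object.
#' @export
read_summary_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  null_to_na <- function(lst) {
    lapply(lst, function(v) if (is.null(v)) NA_real_ else as.numeric(v))
  }
  for (comp in names(x$compartments)) {
    x$compartments[[comp]]$counts <- null_to_na(x$compartments[[comp]]$counts)
    x$compartments[[comp]]$pct <- null_to_na(x$compartments[[comp]]$pct)
  }
  structure(x, class = "concordance_summary")
}
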