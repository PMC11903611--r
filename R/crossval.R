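#' Detection thresholds for cross-platform validation
#'
#' Bundles the detection cutoffs used when re-examining extreme-discordant
#' pairs: mRNA detection (nTPM strictly above `ntpm_detect`, default 0), a
#' stricter mRNA cutoff (nTPM at or above `ntpm_strict`, default 1),
#' mass-spectrometry evidence (mean spectral count at or above
#' `spectral_min`, default 1), and the analogous external RNA-seq cutoffs
#' on TPM.
#'
#' @param ntpm_detect exclusive nTPM detection bound (default 0).
#' @param ntpm_strict inclusive strict nTPM bound (default 1).
#' @param spectral_min inclusive mean-spectral-count bound (default 1).
#' @param tpm_detect exclusive external-TPM detection bound (default 0).
#' @param tpm_strict inclusive strict external-TPM bound (default 1).
#' @return object of class `validation_thresholds`.
#' @export
validation_thresholds <- function(ntpm_detect = 0, ntpm_strict = 1,
                                  spectral_min = 1, tpm_detect = 0,
                                  tpm_strict = 1) {
  vals <- c(ntpm_detect = ntpm_detect, ntpm_strict = ntpm_strict,
            spectral_min = spectral_min, tpm_detect = tpm_detect,
            tpm_strict = tpm_strict)
  if (any(vals < 0)) stop("thresholds must be non-negative", call. = FALSE)
  if (ntpm_strict < ntpm_detect || tpm_strict < tpm_detect) {
    stop("strict thresholds must not be below detection thresholds",
         call. = FALSE)
  }
  structure(as.list(vals), class = "validation_thresholds")
}

# default mapping from pipeline compartments to MS / external-RNA labels
.ms_compartment_map <- c(glomeruli = "glomeruli",
                         tubules = "tubulointerstitium")
.ext_compartment_map <- c(glomeruli = "glomeruli", tubules = "tubules")

#' Validate IHC-undetected proteins against mass spectrometry
#'
#' Takes the pairs with an IHC-undetected protein but detected mRNA
#' (`protein_null_rna_detected`) in one compartment and asks how many have
#' compartment-matched mass-spectrometry evidence. Tubular IHC pairs are
#' matched to the tubulointerstitial MS compartment by default.
#'
#' Genes absent from the MS table are counted as `n_unmatched` — reported
#' separately from genes present but below `spectral_min` — and never as
#' validated.
#'
#' @param pairs paired-record tibble for one compartment.
#' @param ms MS record tibble (`gene_name`, `compartment`,
#'   `mean_spectral_count`) or `NULL` when no MS data are available.
#' @param thresholds a [validation_thresholds()] object.
#' @param compartment_map named map from pair compartments to MS
#'   compartment labels.
#' @return list of counts: `n_detect` (protein-null pairs with nTPM above
#'   the detection bound), `n_strict` (subset at the strict nTPM bound),
#'   `n_ms` (subset with MS evidence; `NA` when MS data are missing),
#'   `n_unmatched`, `n_below`, plus `validated`, the gene-level tibble of
#'   MS-validated pairs.
#' @export
validate_protein_nulls <- function(pairs, ms,
                                   thresholds = validation_thresholds(),
                                   compartment_map = .ms_compartment_map) {
  stopifnot(inherits(thresholds, "validation_thresholds"))
  comp <- unique(as.character(pairs$compartment))
  stopifnot(length(comp) == 1L)
  nulls <- pairs[pairs$discordance_class == "protein_null_rna_detected" &
                   pairs$ntpm > thresholds$ntpm_detect, , drop = FALSE]
  n_detect <- nrow(nulls)
  n_strict <- sum(nulls$ntpm >= thresholds$ntpm_strict)

  ms_comp <- compartment_map[[comp]] %||% comp
  ms_sub <- if (is.null(ms)) NULL else ms[ms$compartment == ms_comp, ,
                                          drop = FALSE]
  if (is.null(ms_sub) || nrow(ms_sub) == 0L) {
    if (!is.null(ms)) {
      warning("no MS records for compartment ", sQuote(ms_comp),
              "; MS validation reported as missing", call. = FALSE)
    }
    return(list(n_detect = n_detect, n_strict = n_strict, n_ms = NA_integer_,
                n_unmatched = NA_integer_, n_below = NA_integer_,
                validated = NULL))
  }
  idx <- match(.norm_key(nulls$gene_name), .norm_key(ms_sub$gene_name))
  counts <- ms_sub$mean_spectral_count[idx]
  hit <- !is.na(idx) & counts >= thresholds$spectral_min
  validated <- nulls[hit, c("gene_id", "gene_name", "compartment", "ntpm"),
                     drop = FALSE]
  validated$mean_spectral_count <- counts[hit]
  list(
    n_detect = n_detect,
    n_strict = n_strict,
    n_ms = sum(hit),
    n_unmatched = sum(is.na(idx)),
    n_below = sum(!is.na(idx) & counts < thresholds$spectral_min),
    validated = validated
  )
}

#' Validate mRNA-undetected pairs against external RNA-seq
#'
#' Takes the pairs with an IHC signal but no detectable mRNA
#' (`rna_null_protein_detected`) in one compartment and asks how many show
#' transcript expression in a compartment-matched external RNA-seq dataset,
#' at the detection (`TPM > tpm_detect`) and strict (`TPM >= tpm_strict`)
#' bounds.
#'
#' @param pairs paired-record tibble for one compartment.
#' @param ext external RNA record tibble (`gene_name`, `compartment`,
#'   `tpm`) or `NULL`.
#' @param thresholds a [validation_thresholds()] object.
#' @param compartment_map named map from pair compartments to external-RNA
#'   compartment labels.
#' @return list of counts `n_total`, `n_tpm_detect`, `n_tpm_strict`
#'   (the latter two `NA` when external data are missing), `n_unmatched`,
#'   plus `validated`, the gene-level tibble of externally detected pairs.
#' @export
validate_rna_nulls <- function(pairs, ext,
                               thresholds = validation_thresholds(),
                               compartment_map = .ext_compartment_map) {
  stopifnot(inherits(thresholds, "validation_thresholds"))
  comp <- unique(as.character(pairs$compartment))
  stopifnot(length(comp) == 1L)
  nulls <- pairs[pairs$discordance_class == "rna_null_protein_detected", ,
                 drop = FALSE]
  n_total <- nrow(nulls)

  ext_comp <- compartment_map[[comp]] %||% comp
  ext_sub <- if (is.null(ext)) NULL else ext[ext$compartment == ext_comp, ,
                                             drop = FALSE]
  if (is.null(ext_sub) || nrow(ext_sub) == 0L) {
    if (!is.null(ext)) {
      warning("no external RNA records for compartment ", sQuote(ext_comp),
              "; external validation reported as missing", call. = FALSE)
    }
    return(list(n_total = n_total, n_tpm_detect = NA_integer_,
                n_tpm_strict = NA_integer_, n_unmatched = NA_integer_,
                validated = NULL))
  }
  idx <- match(.norm_key(nulls$gene_name), .norm_key(ext_sub$gene_name))
  tpm <- ext_sub$tpm[idx]
  detect <- !is.na(idx) & tpm > thresholds$tpm_detect
  validated <- nulls[detect, c("gene_id", "gene_name", "compartment"),
                     drop = FALSE]
  validated$tpm <- tpm[detect]
  list(
    n_total = n_total,
    n_tpm_detect = sum(detect),
    n_tpm_strict = sum(detect & tpm >= thresholds$tpm_strict),
    n_unmatched = sum(is.na(idx)),
    validated = validated
  )
}

#' Assemble the full per-compartment concordance summary
#'
#' Combines the contingency-based concordance counts, the two
#' cross-platform validation results and the chi-square test into one
#' summary object, computing every percentage against the compartment's
#' pair total and enforcing the nesting invariants (strict counts can never
#' exceed their parent counts). A nesting violation is an
#' internal-consistency error.
#'
#' @param concord named list per compartment of [summarize_concordance()]
#'   results.
#' @param protein_val named list per compartment of
#'   [validate_protein_nulls()] results.
#' @param rna_val named list per compartment of [validate_rna_nulls()]
#'   results.
#' @param chi named list per compartment of [chi_square_independence()]
#'   results (optional entries may be `NULL`).
#' @param thresholds the [validation_thresholds()] used.
#' @param diagnostics optional named list per compartment of unmatched-gene
#'   diagnostics.
#' @return object of class `concordance_summary`.
#' @export
assemble_summary <- function(concord, protein_val, rna_val, chi = NULL,
                             thresholds = validation_thresholds(),
                             diagnostics = NULL) {
  comps <- names(concord)
  stopifnot(length(comps) > 0L,
            setequal(comps, names(protein_val)),
            setequal(comps, names(rna_val)))
  compartments <- lapply(comps, function(comp) {
    cc <- concord[[comp]]
    pv <- protein_val[[comp]]
    rv <- rna_val[[comp]]
    if (pv$n_detect != cc$protein_null_rna_detected ||
        rv$n_total != cc$rna_null_protein_detected) {
      stop("validation inputs for ", sQuote(comp),
           " were not computed on the same pair set as the contingency ",
           "summary", call. = FALSE)
    }
    counts <- list(
      total = cc$total,
      concordant = cc$concordant,
      discordant = cc$discordant,
      protein_null_rna_detected = pv$n_detect,
      protein_null_ntpm_strict = pv$n_strict,
      protein_null_ms_validated = pv$n_ms,
      rna_null_protein_detected = rv$n_total,
      rna_null_ext_detected = rv$n_tpm_detect,
      rna_null_ext_strict = rv$n_tpm_strict
    )
    .check_nesting(counts, comp)
    pct <- lapply(counts[-1L], function(n) {
      if (is.na(n)) NA_real_ else pct_of(n, counts$total)
    })
    chi_comp <- chi[[comp]]
    list(
      counts = counts,
      pct = pct,
      chi_square = if (is.null(chi_comp)) NULL else list(
        statistic = chi_comp$statistic,
        degrees_of_freedom = chi_comp$degrees_of_freedom,
        p_value = chi_comp$p_value,
        validity_warning = chi_comp$validity_warning,
        table = "full 4x4 including the Not-detected row and column"
      ),
      diagnostics = c(
        diagnostics[[comp]],
        list(ms_unmatched = pv$n_unmatched, ext_unmatched = rv$n_unmatched)
      )
    )
  })
  names(compartments) <- comps
  structure(
    list(compartments = compartments, thresholds = unclass(thresholds)),
    class = "concordance_summary"
  )
}

# internal: nested counts must be monotone (NA = missing data, not checked)
.check_nesting <- function(counts, comp) {
  le <- function(a, b) is.na(a) || is.na(b) || a <= b
  ok <- counts$concordant + counts$discordant == counts$total &&
    le(counts$protein_null_ms_validated, counts$protein_null_rna_detected) &&
    le(counts$protein_null_ntpm_strict, counts$protein_null_rna_detected) &&
    le(counts$rna_null_ext_strict, counts$rna_null_ext_detected) &&
    le(counts$rna_null_ext_detected, counts$rna_null_protein_detected)
  if (!ok) {
    stop("internal-consistency error: nested counts are not monotone for ",
         "compartment ", sQuote(comp), call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.concordance_summary <- function(x, ...) {
  for (comp in names(x$compartments)) {
    cc <- x$compartments[[comp]]
    cat(sprintf("== %s (n = %d pairs) ==\n", comp, cc$counts$total))
    for (m in setdiff(names(cc$counts), "total")) {
      cat(sprintf("  %-28s %s\n", m,
                  format_count_pct(cc$counts[[m]], cc$counts$total)))
    }
    if (!is.null(cc$chi_square)) {
      cat(sprintf("  chi-square X2 = %.4g, df = %d, p = %.3g\n",
                  cc$chi_square$statistic, cc$chi_square$degrees_of_freedom,
                  cc$chi_square$p_value))
    }
  }
  invisible(x)
}

#' Write the gene lists behind the validated counts
#'
#' One TSV per compartment listing the MS-validated protein-null genes and
#' the externally detected RNA-null genes with their quantitative values.
#'
#' @param protein_val,rna_val per-compartment validation results.
#' @param dir output directory.
#' @return character vector of written paths, invisibly.
#' @export
write_validated_genes <- function(protein_val, rna_val, dir) {
  paths <- character(0)
  for (comp in names(protein_val)) {
    rows <- list()
    pv <- protein_val[[comp]]$validated
    if (!is.null(pv) && nrow(pv) > 0L) {
      rows$ms <- tibble::tibble(
        gene_id = pv$gene_id, gene_name = pv$gene_name,
        evidence = "mass_spectrometry", value = pv$mean_spectral_count
      )
    }
    rv <- rna_val[[comp]]$validated
    if (!is.null(rv) && nrow(rv) > 0L) {
      rows$ext <- tibble::tibble(
        gene_id = rv$gene_id, gene_name = rv$gene_name,
        evidence = "external_rna_seq", value = rv$tpm
      )
    }
    tab <- if (length(rows) > 0L) dplyr::bind_rows(rows) else
      tibble::tibble(gene_id = character(), gene_name = character(),
                     evidence = character(), value = numeric())
    tab <- tab[order(tab$evidence, tab$gene_id), , drop = FALSE]
    path <- file.path(dir, sprintf("validated_genes_%s.tsv", comp))
    readr::write_tsv(tab, path)
    paths <- c(paths, path)
  }
  invisible(paths)
}
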