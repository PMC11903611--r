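#' Pair categorized transcripts with compartment protein records
#'
#' Inner-joins the kidney transcript table with each compartment's IHC
#' bucket on the gene key, so each gene contributes at most one pair per
#' compartment. Genes present on only one side are counted and reported in
#' the `unmatched` attribute, never silently dropped from the bookkeeping.
#'
#' @param transcripts tibble with `gene_id`, `ntpm` and `rna_category`
#'   (from [categorize_transcript()]).
#' @param proteins named list of compartment buckets from
#'   [select_cell_types()], each with `gene_id`, `level`.
#' @param by join key, `"gene_id"` (default) or `"gene_name"`; gene-name
#'   joins are exact and case-insensitive.
#' @param strict if `TRUE`, an empty join for any compartment is an error.
#' @return named list of paired-record tibbles (`gene_id`, `gene_name`,
#'   `compartment`, `ntpm`, `rna_category`, `protein_category`,
#'   `discordance_class`), sorted by gene for deterministic output;
#'   attribute `unmatched` holds per-compartment transcript-only /
#'   protein-only counts.
#' @export
pair_records <- function(transcripts, proteins, by = c("gene_id", "gene_name"),
                         strict = FALSE) {
  by <- match.arg(by)
  stopifnot(is.data.frame(transcripts), is.list(proteins))
  if (!"rna_category" %in% names(transcripts)) {
    stop("transcripts must carry an `rna_category` column; run ",
         "categorize_transcript() first", call. = FALSE)
  }
  tkey <- transcripts[[by]]
  if (by == "gene_name") tkey <- .norm_key(tkey)
  if (anyDuplicated(tkey)) {
    stop("transcript table has duplicate ", by, " keys", call. = FALSE)
  }

  unmatched <- list()
  out <- lapply(names(proteins), function(comp) {
    prot <- proteins[[comp]]
    pkey <- prot[[by]]
    if (by == "gene_name") pkey <- .norm_key(pkey)
    if (anyDuplicated(pkey)) {
      stop("protein bucket ", sQuote(comp), " has duplicate ", by, " keys",
           call. = FALSE)
    }
    idx_t <- match(pkey, tkey)
    hit <- !is.na(idx_t)
    unmatched[[comp]] <<- list(
      transcript_only = sum(!tkey %in% pkey),
      protein_only = sum(!hit)
    )
    if (!any(hit)) {
      if (strict) {
        stop("empty transcript/protein join for compartment ",
             sQuote(comp), call. = FALSE)
      }
      warning("empty transcript/protein join for compartment ",
              sQuote(comp), call. = FALSE)
    }
    pairs <- tibble::tibble(
      gene_id = transcripts$gene_id[idx_t[hit]],
      gene_name = if ("gene_name" %in% names(transcripts)) {
        transcripts$gene_name[idx_t[hit]]
      } else {
        prot$gene_name[hit]
      },
      compartment = comp,
      ntpm = transcripts$ntpm[idx_t[hit]],
      rna_category = transcripts$rna_category[idx_t[hit]],
      protein_category = as_expression_category(prot$level[hit])
    )
    pairs$discordance_class <- classify_pair(pairs$rna_category,
                                             pairs$protein_category)
    pairs[order(pairs$gene_id), , drop = FALSE]
  })
  names(out) <- names(proteins)
  attr(out, "unmatched") <- unmatched
  out
}

#' Classify an mRNA/protein category pair
#'
#' Identical categories are concordant. The two extreme-discordance classes
#' single out pairs where one platform reports nothing while the other
#' detects the gene: `protein_null_rna_detected` (no IHC signal, mRNA
#' detected) and `rna_null_protein_detected` (no mRNA, IHC signal). All
#' remaining disagreements are `discordant_other`.
#'
#' @param rna,protein expression categories (coercible via
#'   [as_expression_category()]); vectors are paired elementwise.
#' @return character vector of discordance classes.
#' @export
classify_pair <- function(rna, protein) {
  rna <- as_expression_category(rna)
  protein <- as_expression_category(protein)
  nd <- expression_levels()[1L]
  dplyr::case_when(
    rna == protein ~ "concordant",
    protein == nd ~ "protein_null_rna_detected",
    rna == nd ~ "rna_null_protein_detected",
    .default = "discordant_other"
  )
}

#' Build the 4x4 ordinal contingency matrix
#'
#' Tabulates paired records into a matrix indexed
#' `[rna_category, protein_category]` over the shared four-level scale.
#'
#' @param pairs paired-record tibble with `rna_category` and
#'   `protein_category`; an attribute `compartment` is attached when the
#'   tibble carries a single compartment label.
#' @return integer matrix of class `contingency_matrix` with dimnames on
#'   [expression_levels()].
#' @export
build_contingency <- function(pairs) {
  stopifnot(is.data.frame(pairs))
  if (nrow(pairs) == 0L) {
    stop("cannot build a contingency matrix from zero pairs", call. = FALSE)
  }
  m <- table(
    rna = as_expression_category(pairs$rna_category),
    protein = as_expression_category(pairs$protein_category)
  )
  m <- unclass(m)
  storage.mode(m) <- "integer"
  comp <- unique(as.character(pairs[["compartment"]]))
  structure(m, class = c("contingency_matrix", class(m)),
            compartment = if (length(comp) == 1L) comp else NULL)
}

#' Concordance and extreme-discordance counts from a contingency matrix
#'
#' The concordant count is the matrix trace; `protein_null_rna_detected`
#' sums the Not-detected protein column over detected mRNA rows, and
#' `rna_null_protein_detected` sums the Not-detected mRNA row over detected
#' protein columns.
#'
#' @param matrix a `contingency_matrix`.
#' @return list of counts (`total`, `concordant`, `discordant`,
#'   `protein_null_rna_detected`, `rna_null_protein_detected`) plus `pct`,
#'   percentages of the total under the reporting convention.
#' @export
summarize_concordance <- function(matrix) {
  stopifnot(inherits(matrix, "contingency_matrix"))
  m <- unclass(matrix)
  total <- sum(m)
  if (total == 0L) stop("empty contingency matrix", call. = FALSE)
  concordant <- sum(diag(m))
  counts <- list(
    total = total,
    concordant = concordant,
    discordant = total - concordant,
    protein_null_rna_detected = sum(m[-1L, 1L]),
    rna_null_protein_detected = sum(m[1L, -1L])
  )
  pct <- lapply(counts[-1L], pct_of, total = total)
  c(counts, list(pct = pct))
}

#' Chi-square test of mRNA/protein independence
#'
#' Pearson chi-square test of independence on the ordinal contingency
#' matrix, without continuity correction. All-zero rows and columns are
#' dropped before computing the degrees of freedom; the statistic sums
#' `(obs - exp)^2 / exp` over the retained cells and the p-value is the
#' upper tail of the chi-square distribution with `(r - 1)(c - 1)` degrees
#' of freedom. `validity_warning` flags any retained expected count below 5.
#'
#' @param matrix a `contingency_matrix` (any non-negative integer matrix
#'   works).
#' @return object of class `chi_square_result`: `statistic`,
#'   `degrees_of_freedom`, `p_value`, `expected_counts`,
#'   `validity_warning`.
#' @export
chi_square_independence <- function(matrix) {
  m <- unclass(matrix)
  stopifnot(is.matrix(m), all(m >= 0))
  keep_r <- rowSums(m) > 0
  keep_c <- colSums(m) > 0
  m <- m[keep_r, keep_c, drop = FALSE]
  if (nrow(m) < 2L || ncol(m) < 2L) {
    stop("independence test undefined: table reduces to a single ",
         "row or column", call. = FALSE)
  }
  total <- sum(m)
  expected <- outer(rowSums(m), colSums(m)) / total
  statistic <- sum((m - expected)^2 / expected)
  df <- (nrow(m) - 1L) * (ncol(m) - 1L)
  structure(
    list(
      statistic = statistic,
      degrees_of_freedom = df,
      p_value = stats::pchisq(statistic, df, lower.tail = FALSE),
      expected_counts = expected,
      validity_warning = any(expected < 5)
    ),
    class = "chi_square_result"
  )
}

#' @export
print.chi_square_result <- function(x, ...) {
  cat(sprintf("Chi-square test of independence: X2 = %.4g, df = %d, p = %.4g%s\n",
              x$statistic, x$degrees_of_freedom, x$p_value,
              if (x$validity_warning) " (expected count < 5 present)" else ""))
  invisible(x)
}

#' Write paired records to TSV
#'
#' One row per mRNA-protein pair with its discordance class, suitable for
#' external stripchart plotting of category correspondence.
#'
#' @param pairs a paired-record tibble, or the per-compartment list from
#'   [pair_records()] (compartments are concatenated).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
emit_pair_table <- function(pairs, path) {
  if (!is.data.frame(pairs)) pairs <- dplyr::bind_rows(pairs)
  stopifnot(is.data.frame(pairs), "discordance_class" %in% names(pairs))
  out <- pairs[order(pairs$compartment, pairs$gene_id), , drop = FALSE]
  out$rna_category <- as.character(out$rna_category)
  out$protein_category <- as.character(out$protein_category)
  readr::write_tsv(out, path)
  invisible(path)
}
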