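#' Published reference counts for the HPA v23.0 kidney concordance analysis
#'
#' Loads the per-compartment count summary (pair totals, concordance and
#' extreme-discordance counts with their reported percentages) published
#' for the Human Protein Atlas v23.0 kidney mRNA-IHC comparison, shipped
#' with the package as a plain-text table. These counts serve as desk-scale
#' inputs: the package's formatting and consistency machinery is run
#' against them rather than against re-downloaded raw data.
#'
#' @return tibble with columns `measure`, `compartment`, `count`,
#'   `reported_pct` (NA for the totals row).
#' @export
reference_counts <- function() {
  path <- system.file("extdata", "kidney_reference_counts.tsv",
                      package = "kidneyconcord", mustWork = TRUE)
  wide <- readr::read_tsv(path, col_types = "cdddd", na = "NA",
                          progress = FALSE)
  long <- tidyr::pivot_longer(
    wide,
    cols = -"measure",
    names_to = c("compartment", ".value"),
    names_pattern = "(glomeruli|tubules)_(count|pct)"
  )
  dplyr::rename(long, reported_pct = "pct")
}

#' Published reference transcript-category counts
#'
#' The whole-kidney transcript census on the shared ordinal scale: genes
#' with zero nTPM (Not detected) and the three tertile categories of the
#' positive values, with the published total.
#'
#' @return tibble with columns `category`, `count`.
#' @export
reference_transcript_categories <- function() {
  path <- system.file("extdata", "kidney_reference_transcript_categories.tsv",
                      package = "kidneyconcord", mustWork = TRUE)
  readr::read_tsv(path, col_types = "cd", progress = FALSE)
}

#' Audit reported counts and percentages for internal consistency
#'
#' Recomputes every percentage from its count and compartment total under
#' the package's reporting convention (round half away from zero, two
#' decimals) and compares it with the reported percentage. Also checks that
#' concordant + discordant reproduce the pair total. A row whose reported
#' percentage cannot be reproduced from its own count is flagged
#' inconsistent.
#'
#' @param counts a tibble as returned by [reference_counts()]; columns
#'   `measure`, `compartment`, `count`, `reported_pct`.
#' @return the input with columns `recomputed_pct` and `consistent`
#'   added; totals rows carry `NA` in both.
#' @export
audit_reported_counts <- function(counts = reference_counts()) {
  stopifnot(all(c("measure", "compartment", "count", "reported_pct")
                %in% names(counts)))
  totals <- counts[counts$measure == "total", c("compartment", "count")]
  if (nrow(totals) == 0L) stop("no `total` rows in input", call. = FALSE)
  idx <- match(counts$compartment, totals$compartment)
  denom <- totals$count[idx]
  recomputed <- ifelse(counts$measure == "total", NA_real_,
                       pct_of(counts$count, denom))
  counts$recomputed_pct <- recomputed
  counts$consistent <- ifelse(
    counts$measure == "total", NA,
    !is.na(recomputed) & !is.na(counts$reported_pct) &
      abs(recomputed - counts$reported_pct) < 1e-9
  )
  counts
}

#' Check additive consistency of reported count families
#'
#' Verifies that (1) reported transcript category counts sum to the
#' reported transcript total and (2) reported concordant + discordant
#' counts reproduce each compartment's pair total.
#'
#' @param counts tibble as from [reference_counts()].
#' @param transcript_categories tibble as from
#'   [reference_transcript_categories()].
#' @return named logical vector with elements `transcript_sum` and one
#'   `pairs_sum_<compartment>` per compartment.
#' @export
check_additivity <- function(counts = reference_counts(),
                             transcript_categories =
                               reference_transcript_categories()) {
  tc <- transcript_categories
  transcript_ok <- sum(tc$count[tc$category != "total"]) ==
    tc$count[tc$category == "total"]
  out <- c(transcript_sum = transcript_ok)
  for (comp in unique(counts$compartment)) {
    sub <- counts[counts$compartment == comp, ]
    get <- function(m) sub$count[sub$measure == m]
    out[[paste0("pairs_sum_", comp)]] <-
      get("concordant") + get("discordant") == get("total")
  }
  out
}
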