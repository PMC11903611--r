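#' The shared ordinal expression scale
#'
#' Both discretized mRNA abundance and semi-quantitative IHC protein calls
#' are expressed on the same four-level ordinal scale:
#' `Not detected < Low < Medium < High`.
#'
#' @return character vector of the four level names in ascending order.
#' @export
expression_levels <- function() {
  c("Not detected", "Low", "Medium", "High")
}

#' Coerce to an ordered expression-category factor
#'
#' @param x character or factor of level names.
#' @return ordered factor over [expression_levels()].
#' @export
as_expression_category <- function(x) {
  x <- as.character(x)
  bad <- !is.na(x) & !x %in% expression_levels()
  if (any(bad)) {
    stop("invalid expression category: ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  factor(x, levels = expression_levels(), ordered = TRUE)
}

# internal: canonical key for case-insensitive, whitespace-flexible matching
.norm_key <- function(x) gsub("\\s+", " ", trimws(tolower(x)))

.level_lookup <- c(
  "not detected" = "Not detected",
  "low" = "Low",
  "medium" = "Medium",
  "high" = "High"
)

.reliability_lookup <- c(
  "enhanced" = "Enhanced",
  "supported" = "Supported",
  "approved" = "Approved",
  "uncertain" = "Uncertain"
)

#' Normalize a raw IHC level string to the ordinal scale
#'
#' Case-folds and trims the input (internal whitespace in "Not detected" is
#' collapsed) and maps it bijectively onto the shared ordinal scale.
#'
#' @param raw character vector of raw level strings.
#' @return ordered factor over [expression_levels()].
#' @export
#' @examples
#' normalize_ihc_level(c("HIGH", "not   detected"))
normalize_ihc_level <- function(raw) {
  key <- .norm_key(raw)
  hit <- .level_lookup[key]
  bad <- is.na(hit) & !is.na(raw)
  if (any(bad)) {
    stop("unrecognized IHC level string(s): ",
         paste(sQuote(unique(raw[bad])), collapse = ", "), call. = FALSE)
  }
  as_expression_category(unname(hit))
}

# internal: same normalization for antibody reliability grades
normalize_reliability <- function(raw) {
  key <- .norm_key(raw)
  hit <- .reliability_lookup[key]
  bad <- is.na(hit) & !is.na(raw)
  if (any(bad)) {
    stop("unrecognized reliability string(s): ",
         paste(sQuote(unique(raw[bad])), collapse = ", "), call. = FALSE)
  }
  unname(hit)
}

#' Drop IHC records with Uncertain antibody reliability
#'
#' Keeps exactly the records whose reliability grade is Enhanced, Supported
#' or Approved; "Uncertain" antibody calls are excluded from all downstream
#' pairing. The number removed is attached as attribute `n_removed`.
#'
#' @param records protein-record tibble with a `reliability` column.
#' @return filtered tibble (possibly empty), with attribute `n_removed`.
#' @export
filter_reliability <- function(records) {
  stopifnot(is.data.frame(records), "reliability" %in% names(records))
  keep <- records$reliability != "Uncertain"
  out <- records[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}

# the seven kidney cell types annotated in the IHC resource
.kidney_cell_types <- c(
  "bowman's capsule", "cells in glomeruli", "cells in tubules",
  "collecting ducts", "distal tubules", "proximal tubules (cell body)",
  "proximal tubules (microvilli)"
)

.compartment_labels <- c(
  "cells in glomeruli" = "glomeruli",
  "cells in tubules" = "tubules"
)

#' Split IHC records into kidney-compartment buckets
#'
#' Keeps only the requested cell types (exact string match after
#' canonicalization -- "distal tubules" is not part of the "tubules" bucket)
#' and returns one bucket per kept cell type, labelled with the canonical
#' compartment name where one exists ("cells in glomeruli" -> "glomeruli",
#' "cells in tubules" -> "tubules").
#'
#' @param records protein-record tibble with a `cell_type` column.
#' @param keep character vector of cell-type strings to retain; defaults to
#'   the glomerular and tubular cell populations.
#' @return named list of tibbles, one per kept cell type; attribute
#'   `n_dropped` counts records of other cell types.
#' @export
select_cell_types <- function(records,
                              keep = c("cells in glomeruli",
                                       "cells in tubules")) {
  stopifnot(is.data.frame(records), "cell_type" %in% names(records))
  keep <- .norm_key(keep)
  if (length(keep) == 0L) {
    stop("`keep` must name at least one cell type", call. = FALSE)
  }
  unknown <- setdiff(keep, .kidney_cell_types)
  if (length(unknown) > 0L) {
    stop("unknown cell type(s) in `keep`: ",
         paste(sQuote(unknown), collapse = ", "), call. = FALSE)
  }
  ct <- .norm_key(records$cell_type)
  buckets <- lapply(keep, function(k) records[ct == k, , drop = FALSE])
  labels <- ifelse(keep %in% names(.compartment_labels),
                   .compartment_labels[keep], keep)
  names(buckets) <- unname(labels)
  attr(buckets, "n_dropped") <- sum(!ct %in% keep)
  buckets
}

#' Tertile thresholds of positive transcript abundance
#'
#' Computes the 1/3 and 2/3 empirical quantiles of the strictly positive
#' nTPM values by linear interpolation between order statistics (probability
#' p maps to rank 1 + (n - 1)p; `stats::quantile` type 7). Zeros are handled
#' separately by the Not-detected rule and never enter the tertiles.
#'
#' @param transcripts transcript tibble with an `ntpm` column, or a bare
#'   numeric vector of nTPM values.
#' @return object of class `tertile_thresholds`: list with `t1`, `t2`
#'   (nTPM boundaries) and `n_positive`.
#' @export
compute_tertiles <- function(transcripts) {
  ntpm <- if (is.data.frame(transcripts)) transcripts$ntpm else transcripts
  stopifnot(is.numeric(ntpm))
  if (any(ntpm < 0, na.rm = TRUE)) {
    stop("nTPM values must be non-negative", call. = FALSE)
  }
  pos <- ntpm[!is.na(ntpm) & ntpm > 0]
  if (length(pos) < 3L) {
    stop("need at least 3 positive nTPM values to form tertiles (got ",
         length(pos), ")", call. = FALSE)
  }
  q <- stats::quantile(pos, probs = c(1, 2) / 3, type = 7, names = FALSE)
  structure(
    list(t1 = q[[1]], t2 = q[[2]], n_positive = length(pos)),
    class = "tertile_thresholds"
  )
}

#' @export
print.tertile_thresholds <- function(x, ...) {
  cat(sprintf(
    "Tertile thresholds on %d positive nTPM values: Low (0, %.4g], Medium (%.4g, %.4g], High (%.4g, Inf)\n",
    x$n_positive, x$t1, x$t1, x$t2, x$t2
  ))
  invisible(x)
}

#' Discretize transcript abundance onto the ordinal scale
#'
#' `ntpm == 0` maps to Not detected; positive values map to Low `(0, t1]`,
#' Medium `(t1, t2]` or High `(t2, Inf)`. Low and Medium are upper-closed so
#' boundary values are classified deterministically.
#'
#' @param ntpm non-negative numeric vector.
#' @param thresholds a `tertile_thresholds` object from [compute_tertiles()].
#' @return ordered factor over [expression_levels()].
#' @export
categorize_transcript <- function(ntpm, thresholds) {
  stopifnot(inherits(thresholds, "tertile_thresholds"))
  if (any(ntpm < 0, na.rm = TRUE)) {
    stop("nTPM values must be non-negative", call. = FALSE)
  }
  lev <- expression_levels()
  out <- ifelse(ntpm == 0, lev[1L],
         ifelse(ntpm <= thresholds$t1, lev[2L],
         ifelse(ntpm <= thresholds$t2, lev[3L], lev[4L])))
  as_expression_category(out)
}
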