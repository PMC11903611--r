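#' Round half away from zero
#'
#' Rounds to `digits` decimals with halves moving away from zero, the
#' convention used for all percentage reporting in this package (base
#' `round()` rounds halves to even).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector, rounded.
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Format a count with its percentage of a total
#'
#' Renders `"N (P%)"` with the percentage rounded half-away-from-zero to two
#' decimals, the layout used in the summary tables.
#'
#' @param count integer vector of counts.
#' @param total positive scalar denominator.
#' @return character vector like `"637 (5.71%)"`; `NA` counts render as
#'   `"missing"`.
#' @export
format_count_pct <- function(count, total) {
  if (length(total) != 1L || is.na(total) || total <= 0) {
    stop("`total` must be a single positive number", call. = FALSE)
  }
  out <- sprintf("%d (%.2f%%)", as.integer(count),
                 round_half_up(100 * count / total, 2))
  out[is.na(count)] <- "missing"
  out
}

#' Percentage of a total, reporting convention
#'
#' @param count numeric vector.
#' @param total positive scalar.
#' @return numeric percentages rounded half-away-from-zero to 2 decimals.
#' @export
pct_of <- function(count, total) {
  round_half_up(100 * count / total, 2)
}

# internal: a structured audit-trail record (stage, metric, value)
audit_record <- function(stage, metric, value) {
  tibble::tibble(stage = stage, metric = metric, value = as.numeric(value))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
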