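#' Round half away from zero
#'
#' Display rounding for percent agreement values. Base `round()` rounds half
#' to even; reported percents use conventional half-up rounding so that, e.g.,
#' 97.75 prints as 97.8.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half away from zero.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  # nudge by an ulp-scale epsilon so values printed at half-boundaries round up
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

#' @noRd
assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

#' @noRd
assert_unique_ids <- function(ids, what) {
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    abort(sprintf(
      "duplicate sample_id in %s: %s",
      what, paste(utils::head(dup, 5), collapse = ", ")
    ))
  }
  invisible(ids)
}

#' Format a proportion as a percent string with one decimal
#' @noRd
fmt_pct <- function(p) {
  ifelse(is.na(p), "NA", sprintf("%.1f%%", round_half_up(100 * p, 1)))
}
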