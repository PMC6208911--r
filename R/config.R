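#' STRAT4 analyte identifiers
#'
#' The four multiplexed mRNA targets, in panel order.
#' @export
STRAT4_ANALYTES <- c("ESR1", "PGR", "ERBB2", "MKI67")

#' Assay configuration for STRAT4 delta-Ct calls
#'
#' Bundles the per-analyte delta-Ct positivity cutoffs and the two CYFIP1
#' reference gates that drive the call cascade: a cartridge is valid only when
#' the CYFIP1 Ct is at most `cyfip1_valid_max`, and a below-cutoff PGR or
#' MKI67 result is reported INDETERMINATE (instead of NEGATIVE) when the
#' CYFIP1 Ct exceeds `cyfip1_input_max`, because low reference amplification
#' signals insufficient sample input to trust a negative for those two
#' analytes.
#'
#' Delta-Ct is `Ct(CYFIP1) - Ct(target)`, so higher values mean more target
#' mRNA relative to the reference. The default cutoffs are the deployed assay
#' settings: -1 for ESR1 and ERBB2, -3.5 for PGR, -4 for MKI67.
#'
#' @param dct_cutoffs Named numeric vector of delta-Ct positivity cutoffs,
#'   one per analyte. A sample is POSITIVE when its delta-Ct is at or above
#'   the cutoff.
#' @param cyfip1_valid_max Maximum CYFIP1 Ct for a valid cartridge (default 35
#'   cycles). Above this (or with no amplification) all four calls are INVALID.
#' @param cyfip1_input_max Maximum CYFIP1 Ct satisfying the minimum-input
#'   requirement for the input-gated analytes (default 31 cycles).
#' @param input_gated Analytes whose below-cutoff results are gated on input
#'   sufficiency (default PGR and MKI67).
#' @return An object of class `strat4_config`.
#' @examples
#' cfg <- strat4_config()
#' cfg$dct_cutoffs
#' @export
strat4_config <- function(dct_cutoffs = c(ESR1 = -1, PGR = -3.5, ERBB2 = -1, MKI67 = -4),
                          cyfip1_valid_max = 35,
                          cyfip1_input_max = 31,
                          input_gated = c("PGR", "MKI67")) {
  if (is.null(names(dct_cutoffs)) || any(!nzchar(names(dct_cutoffs)))) {
    abort("`dct_cutoffs` must be a named numeric vector")
  }
  if (anyDuplicated(names(dct_cutoffs))) {
    abort("`dct_cutoffs` names must be unique (exactly one cutoff per analyte)")
  }
  if (!all(is.finite(dct_cutoffs))) abort("`dct_cutoffs` must be finite")
  if (!is.numeric(cyfip1_valid_max) || !is.numeric(cyfip1_input_max) ||
      cyfip1_input_max >= cyfip1_valid_max) {
    abort("`cyfip1_input_max` must be smaller than `cyfip1_valid_max`")
  }
  bad <- setdiff(input_gated, names(dct_cutoffs))
  if (length(bad) > 0) {
    abort(sprintf("input-gated analyte(s) without a cutoff: %s", paste(bad, collapse = ", ")))
  }
  structure(
    list(
      dct_cutoffs = dct_cutoffs,
      cyfip1_valid_max = cyfip1_valid_max,
      cyfip1_input_max = cyfip1_input_max,
      input_gated = input_gated
    ),
    class = "strat4_config"
  )
}

#' @export
print.strat4_config <- function(x, ...) {
  cat("<strat4_config>\n")
  cat("  delta-Ct cutoffs: ",
      paste(sprintf("%s = %g", names(x$dct_cutoffs), x$dct_cutoffs), collapse = ", "),
      "\n", sep = "")
  cat(sprintf("  CYFIP1 validity gate: Ct <= %g\n", x$cyfip1_valid_max))
  cat(sprintf("  CYFIP1 input gate:    Ct <= %g (applies to %s)\n",
              x$cyfip1_input_max, paste(x$input_gated, collapse = ", ")))
  invisible(x)
}

#' Read or write an assay configuration as YAML
#'
#' The YAML layout mirrors [strat4_config()]; the file shipped at
#' `system.file("extdata", "strat4.yaml", package = "strat4concord")`
#' reproduces the deployed assay cutoffs.
#'
#' @param path Path to a YAML file.
#' @return `read_strat4_config()` returns a `strat4_config`;
#'   `write_strat4_config()` returns `path` invisibly.
#' @export
read_strat4_config <- function(path) {
  y <- yaml::read_yaml(path)
  strat4_config(
    dct_cutoffs = unlist(y$dct_cutoffs),
    cyfip1_valid_max = y$cyfip1_valid_max %||% 35,
    cyfip1_input_max = y$cyfip1_input_max %||% 31,
    input_gated = y$input_gated %||% c("PGR", "MKI67")
  )
}

#' @param config A `strat4_config`.
#' @rdname read_strat4_config
#' @export
write_strat4_config <- function(config, path) {
  stopifnot(inherits(config, "strat4_config"))
  yaml::write_yaml(
    list(
      dct_cutoffs = as.list(config$dct_cutoffs),
      cyfip1_valid_max = config$cyfip1_valid_max,
      cyfip1_input_max = config$cyfip1_input_max,
      input_gated = as.list(config$input_gated)
    ),
    path
  )
  invisible(path)
}
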