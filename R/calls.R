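#' Delta-Ct between the reference and a target transcript
#'
#' Delta-Ct is defined as `Ct(reference) - Ct(target)`. Because Ct falls as
#' template abundance rises, a higher delta-Ct means more target mRNA relative
#' to the reference transcript.
#'
#' Absent measurements (`NA`, no amplification) are a gate condition, not an
#' arithmetic one: callers must handle absence before computing a delta-Ct,
#' so `NA` inputs are an error here.
#'
#' @param ct_reference,ct_target Cycle-threshold values (PCR cycles, finite,
#'   non-negative). Vectorised.
#' @return Numeric vector of delta-Ct values, `ct_reference - ct_target`.
#' @examples
#' compute_dct(30, 30)   # 0
#' compute_dct(28, 29)   # -1, the ESR1/ERBB2 cutoff
#' @export
compute_dct <- function(ct_reference, ct_target) {
  if (anyNA(ct_reference) || anyNA(ct_target)) {
    abort("Ct values must be present; handle no-amplification (NA) before computing delta-Ct")
  }
  if (!all(is.finite(ct_reference) & ct_reference >= 0) ||
      !all(is.finite(ct_target) & ct_target >= 0)) {
    abort("Ct values must be finite and >= 0")
  }
  ct_reference - ct_target
}

# The call cascade, vectorised over samples. Order matters:
#   1. reference absent or above the validity gate       -> INVALID
#   2. delta-Ct at or above the analyte cutoff           -> POSITIVE
#   3. below cutoff, input-gated analyte, reference Ct
#      above the input gate (insufficient sample input)  -> INDETERMINATE
#   4. otherwise                                         -> NEGATIVE
# An absent target with a valid reference is treated as delta-Ct = -Inf
# (no detectable transcript), then gated like any below-cutoff value.
#' @noRd
call_cascade <- function(ct_cyfip1, ct_target, analyte, config) {
  cutoff <- config$dct_cutoffs[[analyte]]
  gated <- analyte %in% config$input_gated

  n <- length(ct_cyfip1)
  ref_absent <- is.na(ct_cyfip1)
  ref_valid <- !ref_absent & ct_cyfip1 <= config$cyfip1_valid_max
  target_absent <- is.na(ct_target)

  dct <- rep(NA_real_, n)
  dct[!ref_absent & !target_absent] <-
    ct_cyfip1[!ref_absent & !target_absent] - ct_target[!ref_absent & !target_absent]
  dct[!ref_absent & target_absent] <- -Inf

  status <- rep("NEGATIVE", n)
  reason <- rep("BELOW_CUTOFF", n)
  reason[target_absent] <- "TARGET_NO_AMPLIFICATION"

  pos <- !is.na(dct) & dct >= cutoff
  status[pos] <- "POSITIVE"
  reason[pos] <- "ABOVE_CUTOFF"

  if (gated) {
    indet <- !pos & !ref_absent & ct_cyfip1 > config$cyfip1_input_max
    status[indet] <- "INDETERMINATE"
    reason[indet] <- "INPUT_INSUFFICIENT"
  }

  invalid <- !ref_valid
  status[invalid] <- "INVALID"
  reason[invalid] <- ifelse(ref_absent[invalid], "REF_NO_AMPLIFICATION", "REF_CT_ABOVE_MAX")

  tibble::tibble(analyte = analyte, dct = dct, status = status, reason = reason)
}

#' Call one analyte from reference and target Ct values
#'
#' Applies the STRAT4 decision cascade for a single analyte. INVALID results
#' (failed reference gate) dominate everything; POSITIVE requires delta-Ct at
#' or above the analyte's cutoff; a below-cutoff PGR or MKI67 with reference
#' Ct above the input gate is INDETERMINATE — the recommended action is to
#' repeat the test with lysate from the entire FFPE section so the reference
#' Ct reaches the input gate; everything else is NEGATIVE.
#'
#' @param ct_cyfip1 CYFIP1 reference Ct values (`NA` = no amplification).
#' @param ct_target Target-analyte Ct values (`NA` = no amplification; with a
#'   valid reference this is treated as delta-Ct of `-Inf`).
#' @param analyte One of `"ESR1"`, `"PGR"`, `"ERBB2"`, `"MKI67"` (or any
#'   analyte named in `config$dct_cutoffs`).
#' @param config A [strat4_config()].
#' @return A tibble with one row per input: `analyte`, `dct`, `status`
#'   (POSITIVE/NEGATIVE/INDETERMINATE/INVALID) and a machine-readable
#'   `reason` code.
#' @examples
#' call_analyte(32, 36.5, "PGR")    # dCt -4.5 < -3.5, input gate failed: INDETERMINATE
#' call_analyte(30, 34.5, "MKI67")  # dCt -4.5 < -4, input ok: NEGATIVE
#' @export
call_analyte <- function(ct_cyfip1, ct_target, analyte, config = strat4_config()) {
  stopifnot(inherits(config, "strat4_config"))
  if (length(analyte) != 1 || !analyte %in% names(config$dct_cutoffs)) {
    abort(sprintf("unknown analyte %s: no delta-Ct cutoff configured", toString(analyte)))
  }
  if (length(ct_target) != length(ct_cyfip1)) {
    abort("`ct_cyfip1` and `ct_target` must have the same length")
  }
  validate_ct(ct_cyfip1, "ct_cyfip1")
  validate_ct(ct_target, "ct_target")
  call_cascade(ct_cyfip1, ct_target, analyte, config)
}

#' @noRd
validate_ct <- function(x, what) {
  bad <- !is.na(x) & (!is.finite(x) | x < 0)
  if (any(bad)) abort(sprintf("%s contains non-finite or negative Ct values", what))
  invisible(x)
}

#' Call the full four-analyte panel for a table of cartridge runs
#'
#' One cartridge measures all four targets against a single CYFIP1 reference,
#' so a failed reference gate invalidates all four calls for that sample.
#'
#' @param panels A data frame with columns `sample_id`, `ct_esr1`, `ct_pgr`,
#'   `ct_erbb2`, `ct_mki67`, `ct_cyfip1`. `NA` means no amplification.
#' @param config A [strat4_config()].
#' @return A tibble in long format, one row per sample x analyte:
#'   `sample_id`, `analyte`, `dct`, `status`, `reason`.
#' @examples
#' panels <- tibble::tibble(
#'   sample_id = c("s1", "s2"),
#'   ct_esr1 = c(27, 33), ct_pgr = c(29, 36), ct_erbb2 = c(31, 32),
#'   ct_mki67 = c(32, 35), ct_cyfip1 = c(30, NA)
#' )
#' call_panel(panels)
#' @export
call_panel <- function(panels, config = strat4_config()) {
  stopifnot(inherits(config, "strat4_config"))
  ct_cols <- paste0("ct_", tolower(STRAT4_ANALYTES))
  assert_columns(panels, c("sample_id", ct_cols, "ct_cyfip1"), "`panels`")
  assert_unique_ids(panels$sample_id, "`panels`")
  validate_ct(panels$ct_cyfip1, "ct_cyfip1")

  purrr::map2_dfr(STRAT4_ANALYTES, ct_cols, function(analyte, col) {
    validate_ct(panels[[col]], col)
    dplyr::bind_cols(
      tibble::tibble(sample_id = panels$sample_id),
      call_cascade(panels$ct_cyfip1, panels[[col]], analyte, config)
    )
  }) |>
    dplyr::arrange(match(.data$sample_id, panels$sample_id))
}

#' Read a Ct panel CSV / write a calls CSV
#'
#' The panel CSV has header
#' `sample_id,ct_esr1,ct_pgr,ct_erbb2,ct_mki67,ct_cyfip1`; an empty field
#' means no amplification. The calls CSV has one row per sample x analyte
#' with columns `sample_id,analyte,dct,status,reason`.
#'
#' @param path File path.
#' @return `read_ct_panels()` returns a tibble of panels; `write_calls()`
#'   returns `path` invisibly.
#' @export
read_ct_panels <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      sample_id = readr::col_character(),
      .default = readr::col_double()
    )
  )
}

#' @param calls A calls tibble from [call_panel()].
#' @rdname read_ct_panels
#' @export
write_calls <- function(calls, path) {
  readr::write_csv(calls, path)
  invisible(path)
}
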