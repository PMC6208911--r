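#' Construct a 2x2 agreement table
#'
#' Cell layout follows the reporting convention for index-test-vs-reference
#' agreement: `a` = reference+/test+, `b` = reference-/test+,
#' `c` = reference+/test-, `d` = reference-/test-. An exclusion ledger
#' records every sample dropped before tabulation and why, so that
#' `n_input = a + b + c + d + n_excluded` always holds.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @param excluded Optional tibble ledger with columns `sample_id`, `reason`.
#' @param configuration Optional named list describing the analysis
#'   (analyte, comparator rule, stratum, ...), carried into reports.
#' @return An object of class `contingency_table`.
#' @examples
#' contingency_table(407, 4, 7, 75)  # ER at the 1% IHC cutoff
#' @export
contingency_table <- function(a, b, c, d, excluded = NULL, configuration = list()) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    abort("cell counts must be non-negative integers")
  }
  if (is.null(excluded)) {
    excluded <- tibble::tibble(sample_id = character(), reason = character())
  }
  structure(
    list(
      a = as.integer(a), b = as.integer(b), c = as.integer(c), d = as.integer(d),
      n = as.integer(a + b + c + d),
      excluded = tibble::as_tibble(excluded),
      configuration = configuration
    ),
    class = "contingency_table"
  )
}

#' @export
print.contingency_table <- function(x, ...) {
  cat("<contingency_table>")
  if (length(x$configuration) > 0) {
    cat(" ", paste(unlist(x$configuration), collapse = " / "), sep = "")
  }
  cat("\n")
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, 2, byrow = TRUE,
              dimnames = list(c("test+", "test-"), c("ref+", "ref-")))
  print(m)
  cat(sprintf("n = %d in table, %d excluded", x$n, nrow(x$excluded)))
  if (nrow(x$excluded) > 0) {
    tab <- table(x$excluded$reason)
    cat(" (", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), ")", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' @export
tidy.contingency_table <- function(x, ...) {
  tibble::tibble(
    reference = c("POSITIVE", "NEGATIVE", "POSITIVE", "NEGATIVE"),
    test = c("POSITIVE", "POSITIVE", "NEGATIVE", "NEGATIVE"),
    cell = c("a", "b", "c", "d"),
    n = c(x$a, x$b, x$c, x$d)
  )
}

# Status vocabularies that count as positive / negative on each axis;
# everything else is excluded with a ledger reason.
call_positive <- "POSITIVE"
call_negative <- "NEGATIVE"
ref_positive <- c("POSITIVE", "HIGH")
ref_negative <- c("NEGATIVE", "LOW")

#' Build the 2x2 agreement table from calls and reference statuses
#'
#' Joins one analyte's RT-qPCR calls to one comparator rule's reference
#' statuses on `sample_id` and tabulates agreement. Samples are sent to the
#' exclusion ledger rather than the table when the call is INVALID (failed
#' reference-gene gate) or INDETERMINATE (insufficient input for a negative),
#' when the reference status is EQUIVOCAL (HER2 2+ under the exclusion
#' policy), INTERMEDIATE (Ki67 zone rules) or UNRESOLVED (2+ without FISH),
#' or when either side is missing.
#'
#' @param calls Tibble with columns `sample_id`, `status` (one analyte's rows
#'   from [call_panel()]).
#' @param reference Tibble with columns `sample_id`, `status` (one rule's rows
#'   from [score_reference()]). POSITIVE/HIGH count as reference-positive,
#'   NEGATIVE/LOW as reference-negative.
#' @param configuration Optional named list describing the analysis.
#' @return A [contingency_table()].
#' @export
build_table <- function(calls, reference, configuration = list()) {
  assert_columns(calls, c("sample_id", "status"), "`calls`")
  assert_columns(reference, c("sample_id", "status"), "`reference`")
  assert_unique_ids(calls$sample_id, "`calls`")
  assert_unique_ids(reference$sample_id, "`reference`")

  joined <- dplyr::full_join(
    dplyr::select(calls, "sample_id", call_status = "status"),
    dplyr::select(reference, "sample_id", ref_status = "status"),
    by = "sample_id"
  ) |>
    dplyr::mutate(
      reason = dplyr::case_when(
        is.na(.data$call_status) | is.na(.data$ref_status) ~ "MISSING",
        .data$call_status == "INVALID" ~ "INVALID",
        .data$call_status == "INDETERMINATE" ~ "INDETERMINATE",
        .data$ref_status == "EQUIVOCAL" ~ "IHC_EQUIVOCAL_EXCLUDED",
        .data$ref_status == "UNRESOLVED" ~ "UNRESOLVED",
        .data$ref_status == "INTERMEDIATE" ~ "IHC_EQUIVOCAL_EXCLUDED",
        TRUE ~ NA_character_
      )
    )

  kept <- dplyr::filter(joined, is.na(.data$reason))
  excluded <- joined |>
    dplyr::filter(!is.na(.data$reason)) |>
    dplyr::select("sample_id", "reason")

  rp <- kept$ref_status %in% ref_positive
  cp <- kept$call_status %in% call_positive
  contingency_table(
    a = sum(rp & cp), b = sum(!rp & cp), c = sum(rp & !cp), d = sum(!rp & !cp),
    excluded = excluded, configuration = configuration
  )
}
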