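#' The standard analysis configurations
#'
#' One row per analyte x comparator-rule combination reported for the assay:
#' ER and PR at both the 1% and 10% IHC cutoffs, HER2 under the three
#' policies (IHC with reflex FISH resolution of 2+, IHC excluding 2+
#' equivocals, FISH alone) plus the IHC+FISH comparison within the
#' ER-positive and ER-negative subsets, and Ki67 at the 20% and 10% single
#' cutoffs — eleven analyses in all.
#'
#' @return A tibble with columns `label`, `analyte`, `rule_id`, `stratum`.
#' @export
table1_analyses <- function() {
  tibble::tribble(
    ~label,                                ~analyte, ~rule_id,              ~stratum,
    "ESR1 (ER), 1% IHC cutoff",            "ESR1",   "er_1pct",             NA_character_,
    "ESR1 (ER), 10% IHC cutoff",           "ESR1",   "er_10pct",            NA_character_,
    "PGR (PR), 1% IHC cutoff",             "PGR",    "pr_1pct",             NA_character_,
    "PGR (PR), 10% IHC cutoff",            "PGR",    "pr_10pct",            NA_character_,
    "ERBB2 (HER2), IHC + FISH",            "ERBB2",  "her2_ihc_fish",       NA_character_,
    "ERBB2 (HER2), IHC excluding 2+",      "ERBB2",  "her2_ihc_excl2plus",  NA_character_,
    "ERBB2 (HER2), FISH only",             "ERBB2",  "her2_fish_only",      NA_character_,
    "ERBB2 (HER2), IHC + FISH, in ER+",    "ERBB2",  "her2_ihc_fish",       "ER_POSITIVE",
    "ERBB2 (HER2), IHC + FISH, in ER-",    "ERBB2",  "her2_ihc_fish",       "ER_NEGATIVE",
    "MKI67 (Ki67), 20% IHC cutoff",        "MKI67",  "ki67_20pct",          NA_character_,
    "MKI67 (Ki67), 10% IHC cutoff",        "MKI67",  "ki67_10pct",          NA_character_
  )
}

# samples usable for ROC / cutoff optimisation for one analyte x rule:
# valid cartridge, finite delta-Ct, binary reference status
#' @noRd
analysis_scores <- function(calls, reference, analyte, rule_id) {
  calls |>
    dplyr::filter(.data$analyte == !!analyte, .data$status != "INVALID",
                  is.finite(.data$dct)) |>
    dplyr::inner_join(
      dplyr::filter(reference, .data$rule_id == !!rule_id) |>
        dplyr::select("sample_id", ref_status = "status"),
      by = "sample_id"
    ) |>
    dplyr::filter(.data$ref_status %in% c(ref_positive, ref_negative)) |>
    dplyr::transmute(
      sample_id = .data$sample_id,
      dct = .data$dct,
      positive = .data$ref_status %in% ref_positive
    )
}

#' Run the full call / score / concordance pipeline
#'
#' Converts a table of cartridge Ct panels into per-analyte calls, scores the
#' IHC/FISH observations under the standard reference rules, and computes one
#' agreement report per configured analysis (counts, PPA, NPA, kappa and OPA,
#' each with its confidence interval), with exclusion bookkeeping throughout.
#' ER-stratified analyses use the ER status at the 1% IHC cutoff as the
#' stratifier.
#'
#' @param panels Ct panel tibble; see [call_panel()].
#' @param ihc IHC observation tibble; see [score_reference()].
#' @param fish Optional FISH tibble.
#' @param config A [strat4_config()].
#' @param analyses Analysis configurations, defaulting to [table1_analyses()].
#' @param ci_method,conf_level Passed to [agreement_stats()].
#' @return An object of class `concordance_run`: `calls`, `reference`,
#'   `reports` (named list of [agreement_stats()] results) and `report`
#'   (one summary row per analysis; also returned by `tidy()`).
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n_samples = 200, seed = 11))
#' run <- run_concordance(cohort$panels, cohort$ihc, cohort$fish)
#' tidy(run)
#' @export
run_concordance <- function(panels, ihc, fish = NULL,
                            config = strat4_config(),
                            analyses = table1_analyses(),
                            ci_method = "clopper_pearson",
                            conf_level = 0.95) {
  assert_columns(analyses, c("label", "analyte", "rule_id", "stratum"), "`analyses`")
  calls <- call_panel(panels, config)
  reference <- score_reference(ihc, fish)

  er_status <- reference |>
    dplyr::filter(.data$rule_id == "er_1pct") |>
    dplyr::select("sample_id", er = "status")

  reports <- purrr::pmap(analyses, function(label, analyte, rule_id, stratum) {
    an_calls <- dplyr::filter(calls, .data$analyte == !!analyte)
    an_ref <- dplyr::filter(reference, .data$rule_id == !!rule_id)
    if (!is.na(stratum)) {
      want <- if (stratum == "ER_POSITIVE") "POSITIVE" else "NEGATIVE"
      keep <- er_status$sample_id[er_status$er == want]
      an_calls <- dplyr::filter(an_calls, .data$sample_id %in% keep)
      an_ref <- dplyr::filter(an_ref, .data$sample_id %in% keep)
    }
    tab <- build_table(an_calls, an_ref,
                       configuration = list(label = label, analyte = analyte,
                                            rule_id = rule_id, stratum = stratum))
    if (tab$n == 0) {
      warning(sprintf("analysis '%s' has no analysable samples; statistics undefined",
                      label))
      return(undefined_report(tab, ci_method, conf_level))
    }
    agreement_stats(tab, ci_method = ci_method, conf_level = conf_level)
  })
  names(reports) <- analyses$label

  report <- dplyr::bind_cols(
    analyses,
    purrr::map_dfr(reports, glance)
  )

  structure(
    list(calls = calls, reference = reference, reports = reports,
         report = report, config = config, ci_method = ci_method,
         conf_level = conf_level),
    class = "concordance_run"
  )
}

#' @export
tidy.concordance_run <- function(x, ...) x$report

#' @export
print.concordance_run <- function(x, ...) {
  cat(sprintf("<concordance_run> %d analyses, %s %g%% CIs\n",
              nrow(x$report), x$ci_method, 100 * x$conf_level))
  df <- x$report
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    cat(sprintf("  %-36s a=%3d b=%3d c=%3d d=%3d n=%3d | PPA %s NPA %s kappa %s OPA %s\n",
                r$label, r$a, r$b, r$c, r$d, r$n,
                fmt_pct(r$ppa), fmt_pct(r$npa), fmt_pct(r$kappa), fmt_pct(r$opa)))
  }
  invisible(x)
}

#' Concordance reports within strata
#'
#' Splits samples by a stratifying label (for example ER status by IHC) and
#' runs the same table-building and agreement machinery within each stratum.
#'
#' @param calls One analyte's calls (`sample_id`, `status`).
#' @param reference One rule's reference statuses (`sample_id`, `status`).
#' @param strata Tibble with columns `sample_id`, `stratum`.
#' @param ci_method,conf_level Passed to [agreement_stats()].
#' @return A named list of [agreement_stats()] reports, one per stratum;
#'   an empty stratum yields `NULL` with a warning rather than an error.
#' @export
stratified_concordance <- function(calls, reference, strata,
                                   ci_method = "clopper_pearson",
                                   conf_level = 0.95) {
  assert_columns(strata, c("sample_id", "stratum"), "`strata`")
  levels <- unique(strata$stratum)
  out <- purrr::map(levels, function(s) {
    ids <- strata$sample_id[strata$stratum == s]
    tab <- build_table(
      dplyr::filter(calls, .data$sample_id %in% ids),
      dplyr::filter(reference, .data$sample_id %in% ids),
      configuration = list(stratum = s)
    )
    if (tab$n == 0) {
      warning(sprintf("stratum %s has no analysable samples; report undefined", s))
      return(NULL)
    }
    agreement_stats(tab, ci_method = ci_method, conf_level = conf_level)
  })
  setNames(out, levels)
}

#' Write the outputs of a concordance run
#'
#' Emits `calls.csv` (per-sample calls), `status.csv` (reference statuses),
#' `report.csv` (one row per analysis with counts and statistics as
#' proportions) and, when jsonlite is installed, `report.json` with the same
#' content for machine consumption.
#'
#' @param run A `concordance_run`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_concordance <- function(run, dir) {
  stopifnot(inherits(run, "concordance_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(run$calls, file.path(dir, "calls.csv"))
  readr::write_csv(run$reference, file.path(dir, "status.csv"))
  readr::write_csv(run$report, file.path(dir, "report.csv"))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(run$report, file.path(dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Plot delta-Ct values by reference category
#'
#' Strip plot of one analyte's delta-Ct values grouped by the comparator
#' status, with the assay cutoff drawn as a horizontal line — the package's
#' analogue of the per-analyte concordance scatterplots.
#'
#' @param run A `concordance_run`.
#' @param analyte One of the panel analytes.
#' @param rule_id A reference rule present in `run$reference`.
#' @return A ggplot object.
#' @export
plot_dct_by_reference <- function(run, analyte, rule_id) {
  stopifnot(inherits(run, "concordance_run"))
  df <- run$calls |>
    dplyr::filter(.data$analyte == !!analyte, is.finite(.data$dct)) |>
    dplyr::inner_join(
      dplyr::filter(run$reference, .data$rule_id == !!rule_id) |>
        dplyr::select("sample_id", ref_status = "status"),
      by = "sample_id"
    )
  cutoff <- run$config$dct_cutoffs[[analyte]]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ref_status, y = .data$dct)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 0.8) +
    ggplot2::geom_hline(yintercept = cutoff, linetype = "dashed", colour = "red") +
    ggplot2::labs(
      x = sprintf("Reference status (%s)", rule_id),
      y = sprintf("%s delta-Ct", analyte),
      title = sprintf("%s delta-Ct by reference category (cutoff %g)", analyte, cutoff)
    ) +
    ggplot2::theme_minimal()
}
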