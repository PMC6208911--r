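#' H-score from intensity fractions
#'
#' The H-score combines extent and intensity of immunohistochemical staining:
#' `3 * (% tumor cells staining 3+) + 2 * (% staining 2+) + 1 * (% staining 1+)`,
#' giving a value from 0 (no staining) to 300 (all cells at maximal intensity).
#'
#' @param pct_1plus,pct_2plus,pct_3plus Percent of tumor cells staining at
#'   intensity 1+, 2+ and 3+ (each 0-100; together at most 100). Vectorised.
#' @return Numeric H-score in `[0, 300]`.
#' @examples
#' h_score(10, 20, 30)  # 140
#' @export
h_score <- function(pct_1plus, pct_2plus, pct_3plus) {
  frac <- cbind(pct_1plus, pct_2plus, pct_3plus)
  ok <- is.na(frac) | (frac >= 0 & frac <= 100)
  if (!all(ok)) abort("intensity fractions must lie in [0, 100]")
  total <- pct_1plus + pct_2plus + pct_3plus
  if (any(!is.na(total) & total > 100 + 1e-9)) {
    abort("intensity fractions sum to more than 100% of tumor cells")
  }
  1 * pct_1plus + 2 * pct_2plus + 3 * pct_3plus
}

#' Hormone-receptor (ER/PR) positivity from percent staining
#'
#' A specimen is receptor-positive when at least `cutoff` percent of tumor
#' cells stain. The two cutoffs in routine use are 1% (ASCO/CAP 2010) and
#' 10%; they disagree exactly on the "low positive" 1-9% stratum.
#'
#' @param percent_positive Percent of tumor cells staining (0-100, real).
#' @param cutoff Positivity cutoff in percent; 1 or 10 unless
#'   `allow_nonstandard = TRUE`.
#' @param allow_nonstandard Permit cutoffs other than 1 or 10.
#' @return Character vector, `"POSITIVE"` or `"NEGATIVE"`.
#' @examples
#' hormone_receptor_status(5, cutoff = 1)   # POSITIVE
#' hormone_receptor_status(5, cutoff = 10)  # NEGATIVE
#' @export
hormone_receptor_status <- function(percent_positive, cutoff = 1,
                                    allow_nonstandard = FALSE) {
  validate_percent(percent_positive)
  if (!allow_nonstandard && !cutoff %in% c(1, 10)) {
    abort("hormone-receptor cutoff must be 1 or 10 (set `allow_nonstandard = TRUE` to override)")
  }
  ifelse(percent_positive >= cutoff, "POSITIVE", "NEGATIVE")
}

#' HER2 status from the IHC category alone
#'
#' @param category HER2 IHC category: `"0"`, `"1+"`, `"2+"` or `"3+"`.
#' @return `"NEGATIVE"` (0/1+), `"EQUIVOCAL"` (2+) or `"POSITIVE"` (3+).
#' @export
her2_ihc_status <- function(category) {
  bad <- !is.na(category) & !category %in% c("0", "1+", "2+", "3+")
  if (any(bad)) {
    abort(sprintf("invalid HER2 IHC category: %s",
                  paste(unique(category[bad]), collapse = ", ")))
  }
  dplyr::case_when(
    is.na(category) ~ NA_character_,
    category %in% c("0", "1+") ~ "NEGATIVE",
    category == "2+" ~ "EQUIVOCAL",
    TRUE ~ "POSITIVE"
  )
}

#' HER2 status from the FISH HER2/CEP17 ratio
#'
#' Amplified (POSITIVE) when the HER2/CEP17 ratio is at or above
#' `ratio_cutoff`; the default 2.0 is the dual-probe ratio criterion of the
#' ASCO/CAP 2013 guideline. Only the ratio arm is implemented — average
#' HER2 copy-number criteria are out of scope.
#'
#' @param her2_cep17_ratio HER2/CEP17 signal ratio (positive real).
#' @param ratio_cutoff Amplification cutoff (default 2.0).
#' @return Character vector, `"POSITIVE"` or `"NEGATIVE"`.
#' @export
her2_fish_status <- function(her2_cep17_ratio, ratio_cutoff = 2.0) {
  bad <- !is.na(her2_cep17_ratio) & (!is.finite(her2_cep17_ratio) | her2_cep17_ratio <= 0)
  if (any(bad)) abort("HER2/CEP17 ratios must be finite and positive")
  ifelse(her2_cep17_ratio >= ratio_cutoff, "POSITIVE", "NEGATIVE")
}

#' Combined HER2 status: IHC with reflex FISH resolution of 2+ equivocals
#'
#' IHC 3+ is POSITIVE and 0/1+ is NEGATIVE on IHC alone; the equivocal 2+
#' category is resolved by FISH when a ratio is available and is otherwise
#' UNRESOLVED. FISH is consulted only for 2+ specimens — the IHC call stands
#' for unequivocal categories.
#'
#' @param category HER2 IHC category as in [her2_ihc_status()].
#' @param her2_cep17_ratio FISH ratio (`NA` = FISH not performed). Vectorised
#'   with `category`.
#' @param ratio_cutoff FISH amplification cutoff (default 2.0).
#' @return `"POSITIVE"`, `"NEGATIVE"` or `"UNRESOLVED"`.
#' @examples
#' her2_combined_status("2+", 3.1)  # POSITIVE (FISH-amplified equivocal)
#' her2_combined_status("2+", NA)   # UNRESOLVED
#' @export
her2_combined_status <- function(category, her2_cep17_ratio = NA_real_,
                                 ratio_cutoff = 2.0) {
  ihc <- her2_ihc_status(category)
  ratio <- rep_len(her2_cep17_ratio, length(ihc))
  dplyr::case_when(
    is.na(ihc) ~ NA_character_,
    ihc != "EQUIVOCAL" ~ ihc,
    is.na(ratio) ~ "UNRESOLVED",
    TRUE ~ her2_fish_status(ratio, ratio_cutoff)
  )
}

#' Ki67 proliferation-rate category from percent staining
#'
#' Two rule families are in use. A single cutoff (10% or 20%) splits samples
#' into HIGH (strictly above the cutoff) versus LOW. A zone rule adds an
#' inclusive intermediate band: LOW below the zone, INTERMEDIATE inside it
#' (bounds included), HIGH above it; the common zones are 10-20% and 10-30%.
#'
#' @param percent_positive Percent of tumor cells staining for Ki67.
#' @param cutoff Single high-proliferation cutoff in percent (default 20).
#'   Ignored when `zone` is given.
#' @param zone Optional length-2 numeric, the inclusive intermediate zone,
#'   e.g. `c(10, 20)`.
#' @return `"HIGH"`/`"LOW"`, plus `"INTERMEDIATE"` under a zone rule.
#' @examples
#' ki67_status(25, cutoff = 20)      # HIGH
#' ki67_status(15, zone = c(10, 30)) # INTERMEDIATE
#' @export
ki67_status <- function(percent_positive, cutoff = 20, zone = NULL) {
  validate_percent(percent_positive)
  if (!is.null(zone)) {
    if (length(zone) != 2 || !is.numeric(zone) || zone[1] >= zone[2]) {
      abort("`zone` must be an increasing pair of percents, e.g. c(10, 20)")
    }
    return(dplyr::case_when(
      is.na(percent_positive) ~ NA_character_,
      percent_positive < zone[1] ~ "LOW",
      percent_positive > zone[2] ~ "HIGH",
      TRUE ~ "INTERMEDIATE"
    ))
  }
  if (!is.numeric(cutoff) || length(cutoff) != 1) abort("`cutoff` must be a single percent")
  ifelse(percent_positive > cutoff, "HIGH", "LOW")
}

#' @noRd
validate_percent <- function(x) {
  bad <- !is.na(x) & (!is.finite(x) | x < 0 | x > 100)
  if (any(bad)) abort("percent values must lie in [0, 100]")
  invisible(x)
}

#' Score IHC/FISH observations under the standard reference rules
#'
#' Applies every configured reference-method rule to a long table of IHC
#' observations (one row per sample x marker) plus an optional FISH table,
#' producing the comparator statuses the concordance stage consumes. The
#' default rule set mirrors the analyses run against the STRAT4 panel:
#' ER and PR at the 1% and 10% cutoffs, HER2 under three policies
#' (IHC with reflex FISH, IHC excluding 2+ equivocals, FISH alone) and Ki67
#' at the 20% and 10% single cutoffs. H-scores are computed for rows carrying
#' intensity fractions.
#'
#' @param ihc Data frame with columns `sample_id`, `marker` (ER/PR/HER2/Ki67),
#'   `percent_positive`, optionally `pct_1plus`, `pct_2plus`, `pct_3plus`
#'   (for H-scores) and `her2_category` (HER2 rows).
#' @param fish Optional data frame with columns `sample_id`,
#'   `her2_cep17_ratio`.
#' @param er_cutoffs,pr_cutoffs Percent cutoffs to evaluate for ER and PR.
#' @param ki67_cutoffs Single cutoffs to evaluate for Ki67.
#' @param her2_policies Subset of `"ihc_plus_fish"`, `"ihc_excluding_2plus"`,
#'   `"fish_only"`.
#' @param fish_ratio_cutoff FISH amplification cutoff (default 2.0).
#' @return A tibble with columns `sample_id`, `marker`, `rule_id`, `status`,
#'   `h_score`. Statuses are POSITIVE/NEGATIVE, EQUIVOCAL (HER2 2+ under the
#'   exclusion policy), UNRESOLVED (2+ without FISH), or HIGH/LOW for Ki67.
#' @export
score_reference <- function(ihc, fish = NULL,
                            er_cutoffs = c(1, 10),
                            pr_cutoffs = c(1, 10),
                            ki67_cutoffs = c(20, 10),
                            her2_policies = c("ihc_plus_fish", "ihc_excluding_2plus", "fish_only"),
                            fish_ratio_cutoff = 2.0) {
  assert_columns(ihc, c("sample_id", "marker", "percent_positive"), "`ihc`")
  her2_policies <- match.arg(her2_policies, several.ok = TRUE)
  if (!is.null(fish)) {
    assert_columns(fish, c("sample_id", "her2_cep17_ratio"), "`fish`")
    assert_unique_ids(fish$sample_id, "`fish`")
  }

  ihc <- tibble::as_tibble(ihc)
  for (col in c("pct_1plus", "pct_2plus", "pct_3plus")) {
    if (!col %in% names(ihc)) ihc[[col]] <- NA_real_
  }
  hs <- function(df) {
    ifelse(
      is.na(df$pct_1plus) | is.na(df$pct_2plus) | is.na(df$pct_3plus),
      NA_real_,
      h_score(
        dplyr::coalesce(df$pct_1plus, 0),
        dplyr::coalesce(df$pct_2plus, 0),
        dplyr::coalesce(df$pct_3plus, 0)
      )
    )
  }

  hormone_rows <- function(marker, cutoffs) {
    df <- dplyr::filter(ihc, .data$marker == !!marker)
    if (nrow(df) == 0) return(NULL)
    assert_unique_ids(df$sample_id, sprintf("`ihc` (%s rows)", marker))
    purrr::map_dfr(cutoffs, function(co) {
      tibble::tibble(
        sample_id = df$sample_id,
        marker = marker,
        rule_id = sprintf("%s_%gpct", tolower(marker), co),
        status = hormone_receptor_status(df$percent_positive, co),
        h_score = hs(df)
      )
    })
  }

  her2_rows <- function() {
    df <- dplyr::filter(ihc, .data$marker == "HER2")
    if (nrow(df) == 0 && is.null(fish)) return(NULL)
    if (nrow(df) > 0) {
      assert_columns(df, "her2_category", "`ihc` (HER2 rows)")
      assert_unique_ids(df$sample_id, "`ihc` (HER2 rows)")
    }
    if (!is.null(fish) && nrow(df) > 0) {
      df <- dplyr::left_join(df, fish, by = "sample_id")
    } else if (nrow(df) > 0) {
      df$her2_cep17_ratio <- NA_real_
    }
    out <- list()
    if ("ihc_plus_fish" %in% her2_policies && nrow(df) > 0) {
      out$combined <- tibble::tibble(
        sample_id = df$sample_id, marker = "HER2", rule_id = "her2_ihc_fish",
        status = her2_combined_status(df$her2_category, df$her2_cep17_ratio,
                                      fish_ratio_cutoff),
        h_score = NA_real_
      )
    }
    if ("ihc_excluding_2plus" %in% her2_policies && nrow(df) > 0) {
      out$excl <- tibble::tibble(
        sample_id = df$sample_id, marker = "HER2", rule_id = "her2_ihc_excl2plus",
        status = her2_ihc_status(df$her2_category),
        h_score = NA_real_
      )
    }
    if ("fish_only" %in% her2_policies && !is.null(fish)) {
      out$fish <- tibble::tibble(
        sample_id = fish$sample_id, marker = "HER2", rule_id = "her2_fish_only",
        status = her2_fish_status(fish$her2_cep17_ratio, fish_ratio_cutoff),
        h_score = NA_real_
      )
    }
    dplyr::bind_rows(out)
  }

  ki67_rows <- function() {
    df <- dplyr::filter(ihc, .data$marker == "Ki67")
    if (nrow(df) == 0) return(NULL)
    assert_unique_ids(df$sample_id, "`ihc` (Ki67 rows)")
    purrr::map_dfr(ki67_cutoffs, function(co) {
      tibble::tibble(
        sample_id = df$sample_id,
        marker = "Ki67",
        rule_id = sprintf("ki67_%gpct", co),
        status = ki67_status(df$percent_positive, cutoff = co),
        h_score = NA_real_
      )
    })
  }

  dplyr::bind_rows(
    hormone_rows("ER", er_cutoffs),
    hormone_rows("PR", pr_cutoffs),
    her2_rows(),
    ki67_rows()
  )
}

#' Read IHC and FISH observation CSVs
#'
#' `read_ihc()` expects header
#' `sample_id,marker,percent_positive,pct_1plus,pct_2plus,pct_3plus,her2_category`
#' (intensity and HER2-category fields may be empty); `read_fish()` expects
#' `sample_id,her2_cep17_ratio`.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_ihc <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      sample_id = readr::col_character(),
      marker = readr::col_character(),
      her2_category = readr::col_character(),
      .default = readr::col_double()
    )
  )
}

#' @rdname read_ihc
#' @export
read_fish <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      sample_id = readr::col_character(),
      her2_cep17_ratio = readr::col_double()
    )
  )
}
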