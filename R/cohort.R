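#' Specification for a synthetic RT-qPCR / IHC / FISH cohort
#'
#' Describes the generative model for a paired biomarker cohort with the
#' statistical structure of a retrospective FFPE breast-cancer collection:
#'
#' * a latent expression state per analyte (prevalences defaulting to the
#'   study margins: ER 0.84, PR 0.74, HER2 0.14, Ki67-high 0.46);
#' * bimodal delta-Ct mixtures for ESR1, PGR and ERBB2 whose components are
#'   placed symmetrically about the assay cutoff (so the generative decision
#'   boundary equals the cutoff), plus a sparse "low positive" stratum for
#'   ER and PR concentrated near the cutoff with 1-9% staining;
#' * a single broad delta-Ct continuum for MKI67, with the latent high/low
#'   label defined by thresholding the latent expression at the prevalence
#'   quantile;
#' * IHC percent staining linked to delta-Ct through a monotone logistic
#'   link with logit-scale noise, and H-score intensity fractions tilted
#'   toward 3+ as delta-Ct rises;
#' * a HER2 IHC category cut from noisy delta-Ct (so 2+ equivocals sit at
#'   intermediate expression) and a FISH HER2/CEP17 ratio increasing
#'   monotonically with ERBB2 delta-Ct, crossing 2.0 at the delta-Ct cutoff;
#' * a CYFIP1 reference Ct drawn from a two-group block-age mixture: old
#'   blocks have degraded RNA (high reference Ct), concentrating cartridge
#'   invalidity (marginal rate about 0.04) and input-insufficiency there.
#'
#' @param n_samples Number of specimens (default 523).
#' @param seed Integer seed; the same spec and seed reproduce the cohort
#'   exactly.
#' @param prevalence Named vector of latent positive-state probabilities.
#' @param dct_params Per-analyte list of mixture parameters: `mean_pos`,
#'   `mean_neg`, `sd` for the two-component analytes; `mean`, `sd` for the
#'   MKI67 continuum; `low_pos_frac`/`low_pos_sd` for the near-cutoff
#'   low-positive stratum of ER and PR.
#' @param link_params Per-marker logistic-link parameters: `scale` (delta-Ct
#'   units per logit) and `noise` (logit-scale SD). The link location is
#'   derived so expected staining crosses the marker's IHC cutoff exactly at
#'   the assay's delta-Ct cutoff.
#' @param cyfip1_params Reference-Ct model: `mean_new`, `sd_new`, `mean_old`,
#'   `sd_old`, `p_old` (old-block fraction) and `p_dropout_old` (probability
#'   of complete reference non-amplification in an old block).
#' @param her2_params HER2 observation model: `cat_breaks` (delta-Ct cuts for
#'   0/1+/2+/3+ after adding `cat_noise`), `ratio_slope`, `ratio_noise`
#'   (log-scale) for the FISH ratio link, and `p_fish` (probability FISH was
#'   performed on a non-equivocal specimen; equivocals are always reflexed).
#' @param config The [strat4_config()] whose cutoffs the mixtures are
#'   anchored to.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_samples = 523,
                        seed = 1,
                        prevalence = c(ESR1 = 0.84, PGR = 0.74, ERBB2 = 0.14, MKI67 = 0.46),
                        dct_params = list(
                          ESR1 = list(mean_pos = 3, mean_neg = -5, sd = 1.5,
                                      low_pos_frac = 0.04, low_pos_sd = 0.7),
                          PGR = list(mean_pos = -0.5, mean_neg = -6.5, sd = 2.2,
                                     low_pos_frac = 0.08, low_pos_sd = 0.9),
                          ERBB2 = list(mean_pos = 2.5, mean_neg = -4.5, sd = 1.4),
                          MKI67 = list(mean = -4, sd = 2.5)
                        ),
                        link_params = list(
                          ER = list(scale = 0.3, noise = 1.5),
                          PR = list(scale = 0.3, noise = 5.5),
                          Ki67 = list(scale = 1.5, noise = 1.65)
                        ),
                        cyfip1_params = list(
                          mean_new = 27.5, sd_new = 1.5,
                          mean_old = 34, sd_old = 2,
                          p_old = 0.115, p_dropout_old = 0.05
                        ),
                        her2_params = list(
                          cat_breaks = c(-4.5, -1.8, 1.8), cat_noise = 1.3,
                          ratio_slope = 0.35, ratio_noise = 0.8, p_fish = 0.62
                        ),
                        config = strat4_config()) {
  stopifnot(inherits(config, "strat4_config"))
  if (n_samples < 1) abort("`n_samples` must be positive")
  if (!all(STRAT4_ANALYTES %in% names(prevalence)) ||
      any(prevalence < 0 | prevalence > 1)) {
    abort("`prevalence` must name all four analytes with probabilities in [0, 1]")
  }
  sds <- c(
    purrr::map_dbl(dct_params[c("ESR1", "PGR", "ERBB2")], "sd"),
    dct_params$MKI67$sd
  )
  if (any(sds <= 0)) abort("delta-Ct component SDs must be positive")
  structure(
    list(
      n_samples = as.integer(n_samples), seed = as.integer(seed),
      prevalence = prevalence, dct_params = dct_params,
      link_params = link_params, cyfip1_params = cyfip1_params,
      her2_params = her2_params, config = config
    ),
    class = "cohort_spec"
  )
}

# logistic link location: expected percent staining crosses `pct_at_cutoff`
# exactly when delta-Ct equals `dct_cutoff`
#' @noRd
link_location <- function(dct_cutoff, pct_at_cutoff, scale) {
  dct_cutoff - scale * stats::qlogis(pct_at_cutoff / 100)
}

#' @noRd
link_percent <- function(dct, dct_cutoff, pct_at_cutoff, scale, noise_sd, n) {
  d0 <- link_location(dct_cutoff, pct_at_cutoff, scale)
  p <- 100 * plogis((dct - d0) / scale + rnorm(n, 0, noise_sd))
  # pathologists report clean zeros below trace staining
  ifelse(p < 0.5, 0, p)
}

# intensity split of percent staining: tilt toward 3+ as delta-Ct rises,
# binomial weights keep f1 + f2 + f3 = percent
#' @noRd
intensity_split <- function(percent, dct, dct_cutoff) {
  w <- plogis((dct - dct_cutoff) / 3)
  tibble::tibble(
    pct_1plus = percent * (1 - w)^2,
    pct_2plus = percent * 2 * w * (1 - w),
    pct_3plus = percent * w^2
  )
}

#' Generate a synthetic paired RT-qPCR / IHC / FISH cohort
#'
#' Draws a cohort from the generative model described in [cohort_spec()]:
#' latent states, delta-Ct values, reference-gene Ct (block-age mixture),
#' target Ct reconstructed as `ct_cyfip1 - dct`, IHC staining through the
#' logistic link, and HER2 category / FISH ratio jointly with ERBB2 delta-Ct.
#' Target Ct above 42 cycles is recorded as no amplification (`NA`).
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `strat4_cohort`: a list of four tibbles —
#'   `panels` (Ct panel per sample), `ihc` (long IHC observations), `fish`
#'   (HER2/CEP17 ratios for the reflexed subset) and `truth` (latent states
#'   and true delta-Ct per sample, plus the old-block flag).
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n_samples = 50, seed = 7))
#' cohort$panels
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(spec$seed, generate_cohort_impl(spec))
}

#' @noRd
generate_cohort_impl <- function(spec) {
  n <- spec$n_samples
  cut <- spec$config$dct_cutoffs
  ids <- sprintf("S%04d", seq_len(n))

  # --- latent states ------------------------------------------------------
  state <- purrr::map(spec$prevalence[c("ESR1", "PGR", "ERBB2")],
                      ~ runif(n) < .x)

  # --- delta-Ct -----------------------------------------------------------
  draw_bimodal <- function(analyte, marker_state) {
    p <- spec$dct_params[[analyte]]
    dct <- ifelse(marker_state,
                  rnorm(n, p$mean_pos, p$sd),
                  rnorm(n, p$mean_neg, p$sd))
    low_pos <- rep(FALSE, n)
    if (!is.null(p$low_pos_frac) && p$low_pos_frac > 0) {
      low_pos <- marker_state & (runif(n) < p$low_pos_frac)
      dct[low_pos] <- rnorm(sum(low_pos), cut[[analyte]], p$low_pos_sd)
    }
    list(dct = dct, low_pos = low_pos)
  }
  esr1 <- draw_bimodal("ESR1", state$ESR1)
  pgr <- draw_bimodal("PGR", state$PGR)
  erbb2 <- draw_bimodal("ERBB2", state$ERBB2)

  mki <- spec$dct_params$MKI67
  z_ki <- rnorm(n, mki$mean, mki$sd)
  ki_threshold <- qnorm(1 - spec$prevalence[["MKI67"]], mki$mean, mki$sd)
  state$MKI67 <- z_ki > ki_threshold

  # --- reference gene (block-age mixture) ---------------------------------
  cy <- spec$cyfip1_params
  old_block <- runif(n) < cy$p_old
  ct_cyfip1 <- ifelse(old_block,
                      rnorm(n, cy$mean_old, cy$sd_old),
                      rnorm(n, cy$mean_new, cy$sd_new))
  ct_cyfip1 <- pmax(ct_cyfip1, 18)
  dropout <- old_block & (runif(n) < cy$p_dropout_old)
  ct_cyfip1[dropout] <- NA_real_

  target_ct <- function(dct) {
    ct <- ct_cyfip1 - dct
    ifelse(is.na(ct) | ct > 42, NA_real_, pmax(ct, 5))
  }
  panels <- tibble::tibble(
    sample_id = ids,
    ct_esr1 = target_ct(esr1$dct),
    ct_pgr = target_ct(pgr$dct),
    ct_erbb2 = target_ct(erbb2$dct),
    ct_mki67 = target_ct(z_ki),
    ct_cyfip1 = ct_cyfip1
  )

  # --- IHC ----------------------------------------------------------------
  lp <- spec$link_params
  pct_er <- link_percent(esr1$dct, cut[["ESR1"]], 1, lp$ER$scale, lp$ER$noise, n)
  pct_pr <- link_percent(pgr$dct, cut[["PGR"]], 1, lp$PR$scale, lp$PR$noise, n)
  pct_er[esr1$low_pos] <- runif(sum(esr1$low_pos), 1, 9)
  pct_pr[pgr$low_pos] <- runif(sum(pgr$low_pos), 1, 9)
  # Ki67 staining crosses the 20% IHC rule at the latent prevalence threshold
  d0_ki <- ki_threshold - lp$Ki67$scale * stats::qlogis(0.20)
  pct_ki <- 100 * plogis((z_ki - d0_ki) / lp$Ki67$scale + rnorm(n, 0, lp$Ki67$noise))

  h2 <- spec$her2_params
  her2_cat <- cut(erbb2$dct + rnorm(n, 0, h2$cat_noise),
                  breaks = c(-Inf, h2$cat_breaks, Inf),
                  labels = c("0", "1+", "2+", "3+"))
  her2_cat <- as.character(her2_cat)

  ihc <- dplyr::bind_rows(
    dplyr::bind_cols(
      tibble::tibble(sample_id = ids, marker = "ER", percent_positive = pct_er),
      intensity_split(pct_er, esr1$dct, cut[["ESR1"]]),
      tibble::tibble(her2_category = NA_character_)
    ),
    dplyr::bind_cols(
      tibble::tibble(sample_id = ids, marker = "PR", percent_positive = pct_pr),
      intensity_split(pct_pr, pgr$dct, cut[["PGR"]]),
      tibble::tibble(her2_category = NA_character_)
    ),
    tibble::tibble(
      sample_id = ids, marker = "HER2", percent_positive = NA_real_,
      pct_1plus = NA_real_, pct_2plus = NA_real_, pct_3plus = NA_real_,
      her2_category = her2_cat
    ),
    tibble::tibble(
      sample_id = ids, marker = "Ki67", percent_positive = pct_ki,
      pct_1plus = NA_real_, pct_2plus = NA_real_, pct_3plus = NA_real_,
      her2_category = NA_character_
    )
  )

  # --- FISH: monotone in ERBB2 delta-Ct, ratio 2.0 at the assay cutoff ----
  ratio <- 0.7 + exp(log(1.3) + h2$ratio_slope * (erbb2$dct - cut[["ERBB2"]]) +
                       rnorm(n, 0, h2$ratio_noise))
  has_fish <- her2_cat == "2+" | runif(n) < h2$p_fish
  fish <- tibble::tibble(
    sample_id = ids[has_fish],
    her2_cep17_ratio = ratio[has_fish]
  )

  truth <- tibble::tibble(
    sample_id = ids,
    old_block = old_block,
    state_esr1 = state$ESR1, dct_esr1 = esr1$dct, low_pos_er = esr1$low_pos,
    state_pgr = state$PGR, dct_pgr = pgr$dct, low_pos_pr = pgr$low_pos,
    state_erbb2 = state$ERBB2, dct_erbb2 = erbb2$dct,
    state_mki67 = state$MKI67, dct_mki67 = z_ki
  )

  structure(
    list(panels = panels, ihc = ihc, fish = fish, truth = truth, spec = spec),
    class = "strat4_cohort"
  )
}

#' @export
print.strat4_cohort <- function(x, ...) {
  cat(sprintf("<strat4_cohort> %d samples (seed %d)\n",
              x$spec$n_samples, x$spec$seed))
  cat(sprintf("  invalid cartridges (CYFIP1 absent or Ct > %g): %d\n",
              x$spec$config$cyfip1_valid_max,
              sum(is.na(x$panels$ct_cyfip1) |
                    x$panels$ct_cyfip1 > x$spec$config$cyfip1_valid_max)))
  cat(sprintf("  FISH performed on %d samples\n", nrow(x$fish)))
  invisible(x)
}

#' Write a synthetic cohort to CSV files
#'
#' Emits `panel.csv`, `ihc.csv`, `fish.csv` and `truth.csv` into `dir`.
#'
#' @param cohort A `strat4_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "strat4_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(cohort$panels, file.path(dir, "panel.csv"))
  readr::write_csv(cohort$ihc, file.path(dir, "ihc.csv"))
  readr::write_csv(cohort$fish, file.path(dir, "fish.csv"))
  readr::write_csv(cohort$truth, file.path(dir, "truth.csv"))
  invisible(dir)
}

#' End-to-end recovery check on a synthetic cohort
#'
#' Generates a cohort, runs the full call / score / concordance pipeline and
#' reports, per analyte: the ROC AUC against the primary reference rule, the
#' overall agreement, the delta-Ct cutoff recovered by [optimize_cutoff()]
#' together with its error from the generative cutoff, and the agreement of
#' determinate calls with the latent truth. Also reports whether the
#' qualitative AUC ordering ESR1 and ERBB2 above PGR above MKI67 holds.
#'
#' @param spec A [cohort_spec()].
#' @return A list with elements `per_analyte` (tibble) and `auc_ordering_ok`
#'   (logical).
#' @export
roundtrip_check <- function(spec) {
  cohort <- simulate_cohort(spec)
  run <- run_concordance(cohort$panels, cohort$ihc, cohort$fish,
                         config = spec$config)
  cutoffs <- spec$config$dct_cutoffs
  truth_long <- tibble::tibble(
    sample_id = rep(cohort$truth$sample_id, 4),
    analyte = rep(STRAT4_ANALYTES, each = nrow(cohort$truth)),
    true_state = c(cohort$truth$state_esr1, cohort$truth$state_pgr,
                   cohort$truth$state_erbb2, cohort$truth$state_mki67)
  )

  primary_rule <- c(ESR1 = "er_1pct", PGR = "pr_1pct",
                    ERBB2 = "her2_ihc_fish", MKI67 = "ki67_20pct")

  per_analyte <- purrr::map_dfr(STRAT4_ANALYTES, function(an) {
    scored <- analysis_scores(run$calls, run$reference, an, primary_rule[[an]])
    auc <- if (length(unique(scored$positive)) == 2) {
      roc_dct(scored$dct, scored$positive)$auc
    } else {
      NA_real_
    }
    opt <- if (length(unique(scored$positive)) == 2) {
      optimize_cutoff(scored$dct, scored$positive)
    } else {
      tibble::tibble(cutoff = NA_real_, opa = NA_real_)
    }
    tab <- build_table(
      dplyr::filter(run$calls, .data$analyte == an),
      dplyr::filter(run$reference, .data$rule_id == primary_rule[[an]]),
      configuration = list(analyte = an, rule = primary_rule[[an]])
    )
    truth_agree <- run$calls |>
      dplyr::filter(.data$analyte == an,
                    .data$status %in% c("POSITIVE", "NEGATIVE")) |>
      dplyr::inner_join(dplyr::filter(truth_long, .data$analyte == an),
                        by = c("sample_id", "analyte")) |>
      dplyr::summarise(p = mean((.data$status == "POSITIVE") == .data$true_state)) |>
      dplyr::pull("p")
    tibble::tibble(
      analyte = an,
      rule = primary_rule[[an]],
      auc = auc,
      opa = (tab$a + tab$d) / tab$n,
      cutoff_recovered = opt$cutoff,
      cutoff_error = opt$cutoff - cutoffs[[an]],
      truth_agreement = truth_agree
    )
  })

  auc <- setNames(per_analyte$auc, per_analyte$analyte)
  ordering_ok <- !anyNA(auc) &&
    min(auc[["ESR1"]], auc[["ERBB2"]]) > auc[["PGR"]] &&
    auc[["PGR"]] > auc[["MKI67"]]
  list(per_analyte = per_analyte, auc_ordering_ok = ordering_ok)
}
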