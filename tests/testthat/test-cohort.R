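test_that("the same spec and seed reproduce the cohort exactly", {
  spec <- cohort_spec(n_samples = 120, seed = 99)
  c1 <- simulate_cohort(spec)
  c2 <- simulate_cohort(spec)
  expect_identical(c1$panels, c2$panels)
  expect_identical(c1$ihc, c2$ihc)
  expect_identical(c1$fish, c2$fish)
  expect_identical(c1$truth, c2$truth)
  # a different seed changes the draw
  c3 <- simulate_cohort(cohort_spec(n_samples = 120, seed = 100))
  expect_false(identical(c1$panels, c3$panels))
  # and the global RNG stream is untouched
  withr::local_seed(1)
  before <- runif(1)
  withr::local_seed(1)
  invisible(simulate_cohort(spec))
  expect_identical(runif(1), before)
})

test_that("latent positive fractions stay within 3 SE of the spec prevalences", {
  spec <- cohort_spec(n_samples = 2000, seed = 4)
  truth <- simulate_cohort(spec)$truth
  obs <- c(
    ESR1 = mean(truth$state_esr1), PGR = mean(truth$state_pgr),
    ERBB2 = mean(truth$state_erbb2), MKI67 = mean(truth$state_mki67)
  )
  for (an in names(obs)) {
    p <- spec$prevalence[[an]]
    se <- sqrt(p * (1 - p) / spec$n_samples)
    expect_lt(abs(obs[[an]] - p), 3 * se)
  }
})

test_that("expected IHC staining is monotone nondecreasing in delta-Ct", {
  # with link noise removed the percent-staining link must be monotone
  spec <- cohort_spec(
    n_samples = 400, seed = 6,
    link_params = list(
      ER = list(scale = 0.3, noise = 0),
      PR = list(scale = 0.3, noise = 0),
      Ki67 = list(scale = 1.5, noise = 0)
    ),
    dct_params = list(
      ESR1 = list(mean_pos = 3, mean_neg = -5, sd = 1.5, low_pos_frac = 0, low_pos_sd = 0.7),
      PGR = list(mean_pos = -0.5, mean_neg = -6.5, sd = 2.2, low_pos_frac = 0, low_pos_sd = 0.9),
      ERBB2 = list(mean_pos = 2.5, mean_neg = -4.5, sd = 1.4),
      MKI67 = list(mean = -4, sd = 2.5)
    )
  )
  co <- simulate_cohort(spec)
  er <- co$ihc[co$ihc$marker == "ER", ]
  ord <- order(co$truth$dct_esr1)
  expect_true(all(diff(er$percent_positive[ord]) >= 0))
  ki <- co$ihc[co$ihc$marker == "Ki67", ]
  ord <- order(co$truth$dct_mki67)
  expect_true(all(diff(ki$percent_positive[ord]) >= 0))
})

test_that("the FISH ratio rises with ERBB2 expression and crosses 2 near the cutoff", {
  co <- simulate_cohort(cohort_spec(n_samples = 1000, seed = 12))
  joined <- dplyr::inner_join(co$fish, co$truth, by = "sample_id")
  expect_gt(stats::cor(joined$her2_cep17_ratio, joined$dct_erbb2, method = "spearman"), 0.5)
  hi <- mean(joined$her2_cep17_ratio[joined$dct_erbb2 > 0])
  lo <- mean(joined$her2_cep17_ratio[joined$dct_erbb2 < -2])
  expect_gt(hi, 2)
  expect_lt(lo, 2)
})

test_that("cartridge invalidity concentrates in old blocks at about a 4% rate", {
  counts <- vapply(1:100, function(s) {
    co <- simulate_cohort(cohort_spec(n_samples = 523, seed = s))
    sum(is.na(co$panels$ct_cyfip1) | co$panels$ct_cyfip1 > 35)
  }, numeric(1))
  # expected count about 21 of 523
  expect_gt(mean(counts), 15)
  expect_lt(mean(counts), 27)
  co <- simulate_cohort(cohort_spec(n_samples = 4000, seed = 2))
  invalid <- is.na(co$panels$ct_cyfip1) | co$panels$ct_cyfip1 > 35
  expect_gt(mean(co$truth$old_block[invalid]), 0.9)
})

test_that("a noiseless, well-separated spec yields perfect downstream agreement", {
  spec <- cohort_spec(
    n_samples = 300, seed = 3,
    dct_params = list(
      ESR1 = list(mean_pos = 4, mean_neg = -6, sd = 0.2, low_pos_frac = 0, low_pos_sd = 0.5),
      PGR = list(mean_pos = 1, mean_neg = -8, sd = 0.2, low_pos_frac = 0, low_pos_sd = 0.5),
      ERBB2 = list(mean_pos = 4, mean_neg = -6, sd = 0.2),
      MKI67 = list(mean = -4, sd = 2.5)
    ),
    link_params = list(
      ER = list(scale = 0.3, noise = 0),
      PR = list(scale = 0.3, noise = 0),
      Ki67 = list(scale = 1.5, noise = 0)
    ),
    her2_params = list(cat_breaks = c(-4.5, -1.8, 1.8), cat_noise = 0,
                       ratio_slope = 0.35, ratio_noise = 0, p_fish = 1),
    cyfip1_params = list(mean_new = 27.5, sd_new = 1.5, mean_old = 34, sd_old = 2,
                         p_old = 0, p_dropout_old = 0)
  )
  rt <- roundtrip_check(spec)
  for (an in c("ESR1", "PGR", "ERBB2")) {
    row <- rt$per_analyte[rt$per_analyte$analyte == an, ]
    expect_equal(row$opa, 1)
    expect_equal(row$auc, 1)
    expect_equal(row$truth_agreement, 1)
  }
})

test_that("default cohorts land in the calibrated agreement bands", {
  rt <- roundtrip_check(cohort_spec(n_samples = 500, seed = 1))
  opa <- setNames(rt$per_analyte$opa, rt$per_analyte$analyte)
  expect_gte(opa[["ESR1"]], 0.95)
  expect_lte(opa[["ESR1"]], 0.99)
  expect_gte(opa[["MKI67"]], 0.65)
  expect_lte(opa[["MKI67"]], 0.80)
  expect_true(rt$auc_ordering_ok)
  # recovered cutoffs sit near the generative ones
  expect_true(all(abs(rt$per_analyte$cutoff_error) < 2.5))
})

test_that("a single-class degenerate spec reports undefined without crashing", {
  spec <- cohort_spec(
    n_samples = 60, seed = 5,
    prevalence = c(ESR1 = 1, PGR = 0.74, ERBB2 = 0.14, MKI67 = 0.46),
    dct_params = list(
      ESR1 = list(mean_pos = 5, mean_neg = -5, sd = 0.5, low_pos_frac = 0, low_pos_sd = 0.7),
      PGR = list(mean_pos = -0.5, mean_neg = -6.5, sd = 2.2, low_pos_frac = 0.08, low_pos_sd = 0.9),
      ERBB2 = list(mean_pos = 2.5, mean_neg = -4.5, sd = 1.4),
      MKI67 = list(mean = -4, sd = 2.5)
    ),
    link_params = list(
      ER = list(scale = 0.3, noise = 0),
      PR = list(scale = 0.3, noise = 5.5),
      Ki67 = list(scale = 1.5, noise = 1.65)
    )
  )
  expect_warning(rt <- roundtrip_check(spec), "no analysable samples")
  expect_true(is.na(rt$per_analyte$auc[rt$per_analyte$analyte == "ESR1"]))
  expect_false(rt$auc_ordering_ok)
})

test_that("cohort CSVs are written and read back faithfully", {
  dir <- withr::local_tempdir()
  co <- simulate_cohort(cohort_spec(n_samples = 40, seed = 8))
  write_cohort(co, dir)
  expect_setequal(list.files(dir), c("panel.csv", "ihc.csv", "fish.csv", "truth.csv"))
  panels <- read_ct_panels(file.path(dir, "panel.csv"))
  expect_equal(panels$ct_cyfip1, co$panels$ct_cyfip1)
  ihc <- read_ihc(file.path(dir, "ihc.csv"))
  expect_equal(nrow(ihc), nrow(co$ihc))
})
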