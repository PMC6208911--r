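test_that("delta-Ct is reference minus target and rejects absent or invalid input", {
  expect_identical(compute_dct(30, 30), 0)
  expect_identical(compute_dct(28, 29), -1)
  expect_identical(compute_dct(31, 27.5), 3.5)
  expect_identical(compute_dct(c(30, 28), c(30, 29)), c(0, -1))
  expect_error(compute_dct(NA, 30), "absence|no-amplification")
  expect_error(compute_dct(30, -1), "finite")
})

test_that("the call cascade handles each gate in order", {
  # failed validity gate dominates everything, whatever the target shows
  expect_equal(call_analyte(36, 20, "ESR1")$status, "INVALID")
  expect_equal(call_analyte(36, 20, "ESR1")$reason, "REF_CT_ABOVE_MAX")
  expect_equal(call_analyte(NA, 20, "ESR1")$reason, "REF_NO_AMPLIFICATION")
  # below-cutoff PGR with reference above the input gate is INDETERMINATE
  pgr <- call_analyte(32, 36.5, "PGR")
  expect_equal(pgr$status, "INDETERMINATE")
  expect_equal(pgr$dct, -4.5)
  expect_equal(pgr$reason, "INPUT_INSUFFICIENT")
  # same delta-Ct with sufficient input is a trustworthy NEGATIVE
  expect_equal(call_analyte(30, 34.5, "MKI67")$status, "NEGATIVE")
  # ESR1 is not input-gated: above cutoff is POSITIVE regardless
  expect_equal(call_analyte(32, 30, "ESR1")$status, "POSITIVE")
  expect_error(call_analyte(30, 30, "BRCA1"), "unknown analyte")
})

test_that("boundary values are inclusive exactly as specified", {
  # delta-Ct exactly at the cutoff is POSITIVE
  expect_equal(call_analyte(30, 31, "ESR1")$status, "POSITIVE")
  expect_equal(call_analyte(30, 33.5, "PGR")$status, "POSITIVE")
  # reference Ct exactly 35 is still a valid cartridge
  expect_equal(call_analyte(35, 30, "ESR1")$status, "POSITIVE")
  # reference Ct exactly 31 satisfies the input gate: NEGATIVE, not INDETERMINATE
  expect_equal(call_analyte(31, 36, "PGR")$status, "NEGATIVE")
  expect_equal(call_analyte(31 + 1e-9, 36, "PGR")$status, "INDETERMINATE")
})

test_that("status is a step function of delta-Ct and gating is exclusive", {
  cfg <- strat4_config()
  for (analyte in STRAT4_ANALYTES) {
    cutoff <- cfg$dct_cutoffs[[analyte]]
    dct_grid <- cutoff + seq(-3, 3, by = 0.25)
    ref <- 30
    st <- call_analyte(rep(ref, length(dct_grid)), ref - dct_grid, analyte, cfg)$status
    expect_true(all(st[dct_grid >= cutoff] == "POSITIVE"))
    expect_true(all(st[dct_grid < cutoff] != "POSITIVE"))
    # monotone: once positive, stays positive as delta-Ct rises
    expect_true(all(diff(st == "POSITIVE") >= 0))
  }
  # INDETERMINATE never occurs for the non-gated analytes
  for (analyte in c("ESR1", "ERBB2")) {
    st <- call_analyte(rep(34, 50), seq(20, 45, length.out = 50), analyte)$status
    expect_false(any(st == "INDETERMINATE"))
  }
  # INVALID is independent of target values
  st <- call_analyte(rep(36, 4), c(20, 30, 40, NA), "PGR")$status
  expect_true(all(st == "INVALID"))
})

test_that("call_analyte agrees with a brute-force enumeration on the boundary grid", {
  cfg <- strat4_config()
  for (analyte in STRAT4_ANALYTES) {
    cutoff <- cfg$dct_cutoffs[[analyte]]
    for (ref in c(29, 30.9, 31, 31.1, 34.9, 35, 35.1, 37)) {
      for (dct in c(cutoff - 1, cutoff - 0.1, cutoff, cutoff + 0.1, cutoff + 1)) {
        got <- call_analyte(ref, ref - dct, analyte, cfg)$status
        expect_equal(got, oracle_call(ref, ref - dct, analyte),
                     info = sprintf("%s ref=%g dct=%g", analyte, ref, dct))
      }
    }
  }
})

test_that("call_panel yields four calls per sample and shares the reference gate", {
  calls <- call_panel(example_panels())
  expect_equal(nrow(calls), 5 * 4)
  expect_equal(sort(unique(calls$analyte)), sort(STRAT4_ANALYTES))
  # all four calls of an invalid cartridge are INVALID
  for (id in c("invalid_high", "invalid_absent")) {
    expect_true(all(calls$status[calls$sample_id == id] == "INVALID"))
  }
  # absent reference leaves delta-Ct undefined
  expect_true(all(is.na(calls$dct[calls$sample_id == "invalid_absent"])))
  # mixed statuses on one valid cartridge
  indet <- calls[calls$sample_id == "indet", ]
  expect_equal(indet$status[indet$analyte == "PGR"], "INDETERMINATE")
  expect_equal(indet$status[indet$analyte == "ESR1"], "POSITIVE")
  expect_error(call_panel(dplyr::bind_rows(example_panels(), example_panels())),
               "duplicate")
})

test_that("an absent target with a valid reference is below every cutoff", {
  panels <- tibble::tibble(
    sample_id = "s", ct_esr1 = NA, ct_pgr = NA, ct_erbb2 = NA, ct_mki67 = NA,
    ct_cyfip1 = 30
  )
  calls <- call_panel(panels)
  expect_true(all(calls$dct == -Inf))
  expect_true(all(calls$status == "NEGATIVE"))
  expect_true(all(calls$reason == "TARGET_NO_AMPLIFICATION"))
})

test_that("panel and call CSVs round-trip with empty fields as absent", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "panel.csv")
  readr::write_csv(example_panels(), p, na = "")
  panels <- read_ct_panels(p)
  expect_equal(panels$ct_cyfip1, example_panels()$ct_cyfip1)
  calls <- call_panel(panels)
  cp <- file.path(dir, "calls.csv")
  write_calls(calls, cp)
  back <- readr::read_csv(cp, show_col_types = FALSE)
  expect_equal(back$status, calls$status)
})

test_that("the shipped YAML configuration reproduces the deployed cutoffs", {
  cfg <- read_strat4_config(
    system.file("extdata", "strat4.yaml", package = "strat4concord")
  )
  expect_equal(cfg$dct_cutoffs,
               c(ESR1 = -1, PGR = -3.5, ERBB2 = -1, MKI67 = -4))
  expect_equal(cfg$cyfip1_valid_max, 35)
  expect_equal(cfg$cyfip1_input_max, 31)
  # round-trip through write/read preserves the configuration
  dir <- withr::local_tempdir()
  f <- file.path(dir, "cfg.yaml")
  write_strat4_config(cfg, f)
  expect_equal(read_strat4_config(f)$dct_cutoffs, cfg$dct_cutoffs)
  expect_error(strat4_config(cyfip1_valid_max = 31, cyfip1_input_max = 35),
               "smaller")
})
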