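#' Binomial confidence intervals
#'
#' Two interval methods for a binomial proportion `x / n`: the Clopper-Pearson
#' exact interval (beta-quantile form; guaranteed coverage at or above the
#' nominal level) and the Wilson score interval. Clopper-Pearson is the
#' default throughout the package.
#'
#' @param x Number of successes (vectorised).
#' @param n Number of trials.
#' @param conf_level Confidence level (default 0.95).
#' @param method `"clopper_pearson"` or `"wilson"`.
#' @return A tibble with columns `estimate`, `conf.low`, `conf.high`
#'   (proportions).
#' @export
binom_ci <- function(x, n, conf_level = 0.95,
                     method = c("clopper_pearson", "wilson")) {
  method <- match.arg(method)
  if (any(x < 0 | x > n)) abort("`x` must lie in [0, n]")
  alpha <- 1 - conf_level
  p <- x / n
  if (method == "clopper_pearson") {
    lo <- ifelse(x == 0, 0, qbeta(alpha / 2, x, n - x + 1))
    hi <- ifelse(x == n, 1, qbeta(1 - alpha / 2, x + 1, n - x))
  } else {
    z <- qnorm(1 - alpha / 2)
    denom <- 1 + z^2 / n
    centre <- (p + z^2 / (2 * n)) / denom
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
    # exact endpoints at the boundary (centre -/+ half equals them only up to
    # floating-point roundoff)
    lo <- ifelse(x == 0, 0, pmax(0, centre - half))
    hi <- ifelse(x == n, 1, pmin(1, centre + half))
  }
  tibble::tibble(estimate = p, conf.low = lo, conf.high = hi)
}

#' Cohen's kappa for a 2x2 agreement table
#'
#' Chance-corrected agreement `kappa = (po - pe) / (1 - pe)`, where `po` is
#' the observed agreement proportion and `pe` the agreement expected from the
#' marginals. The confidence interval uses the large-sample standard error of
#' Fleiss, Cohen and Everitt for the estimated kappa, `kappa +/- z * SE`,
#' truncated to `[-1, 1]`.
#'
#' @param tab A [contingency_table()].
#' @param conf_level Confidence level (default 0.95).
#' @return A tibble row: `estimate`, `conf.low`, `conf.high`, `se`. All `NA`
#'   when the marginals are degenerate (`pe = 1`).
#' @examples
#' cohen_kappa(contingency_table(407, 4, 7, 75))
#' @export
cohen_kappa <- function(tab, conf_level = 0.95) {
  stopifnot(inherits(tab, "contingency_table"))
  if (tab$n == 0) abort("cannot compute kappa on an empty table")
  n <- tab$n
  # p[i, j]: row i = reference (+, -), column j = index test (+, -)
  p <- matrix(c(tab$a, tab$c, tab$b, tab$d), 2, 2, byrow = TRUE) / n
  row_m <- rowSums(p)
  col_m <- colSums(p)
  po <- sum(diag(p))
  pe <- sum(row_m * col_m)
  if (1 - pe < .Machine$double.eps) {
    return(tibble::tibble(estimate = NA_real_, conf.low = NA_real_,
                          conf.high = NA_real_, se = NA_real_))
  }
  k <- (po - pe) / (1 - pe)

  # Fleiss-Cohen-Everitt asymptotic variance of the sample kappa
  t1 <- sum(diag(p) * ((1 - pe) - (col_m + row_m) * (1 - po))^2)
  t2 <- (1 - po)^2 * (p[1, 2] * (col_m[1] + row_m[2])^2 +
                      p[2, 1] * (col_m[2] + row_m[1])^2)
  t3 <- (po * pe - 2 * pe + po)^2
  # clamp: near-perfect tables can give a tiny negative value in floating point
  se <- sqrt(max(0, (t1 + t2 - t3) / (n * (1 - pe)^4)))

  z <- qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(
    estimate = k,
    conf.low = max(-1, k - z * se),
    conf.high = min(1, k + z * se),
    se = se
  )
}

#' Agreement statistics for an index test against a reference method
#'
#' Computes positive percent agreement (PPA, the sensitivity analogue,
#' `a / (a + c)`), negative percent agreement (NPA, specificity analogue,
#' `d / (b + d)`), overall percent agreement (OPA, `(a + d) / n`) and Cohen's
#' kappa for a 2x2 table, each with a confidence interval. A statistic whose
#' margin is empty is reported as `NA` (undefined); the others are still
#' computed.
#'
#' @param tab A [contingency_table()].
#' @param ci_method Binomial interval method for PPA/NPA/OPA; see [binom_ci()].
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `concordance_report`. Use [tidy()] for the
#'   statistics as proportions with intervals, [glance()] for a one-row
#'   summary; printing shows percents rounded to one decimal.
#' @examples
#' agreement_stats(contingency_table(407, 4, 7, 75))
#' @export
agreement_stats <- function(tab, ci_method = c("clopper_pearson", "wilson"),
                            conf_level = 0.95) {
  stopifnot(inherits(tab, "contingency_table"))
  ci_method <- match.arg(ci_method)
  if (tab$n == 0) abort("cannot compute agreement statistics on an empty table")

  one <- function(x, n) {
    if (n == 0) {
      tibble::tibble(estimate = NA_real_, conf.low = NA_real_, conf.high = NA_real_)
    } else {
      binom_ci(x, n, conf_level, ci_method)
    }
  }
  est <- dplyr::bind_rows(
    ppa = one(tab$a, tab$a + tab$c),
    npa = one(tab$d, tab$b + tab$d),
    opa = one(tab$a + tab$d, tab$n),
    kappa = dplyr::select(cohen_kappa(tab, conf_level), -"se"),
    .id = "statistic"
  )

  structure(
    list(
      estimates = est,
      table = tab,
      n = tab$n,
      ci_method = ci_method,
      conf_level = conf_level,
      configuration = tab$configuration
    ),
    class = "concordance_report"
  )
}

# placeholder report for an empty (degenerate) table: all statistics undefined
#' @noRd
undefined_report <- function(tab, ci_method, conf_level) {
  structure(
    list(
      estimates = tibble::tibble(
        statistic = c("ppa", "npa", "opa", "kappa"),
        estimate = NA_real_, conf.low = NA_real_, conf.high = NA_real_
      ),
      table = tab, n = tab$n, ci_method = ci_method, conf_level = conf_level,
      configuration = tab$configuration
    ),
    class = "concordance_report"
  )
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("<concordance_report>")
  if (length(x$configuration) > 0) {
    cat(" ", paste(unlist(x$configuration), collapse = " / "), sep = "")
  }
  cat(sprintf("  [n = %d, %s %g%% CI]\n", x$n, x$ci_method, 100 * x$conf_level))
  with(x$table, cat(sprintf("  counts: a=%d b=%d c=%d d=%d, excluded=%d\n",
                            a, b, c, d, nrow(excluded))))
  for (i in seq_len(nrow(x$estimates))) {
    row <- x$estimates[i, ]
    cat(sprintf("  %-5s %s (%s-%s)\n", toupper(row$statistic),
                fmt_pct(row$estimate), fmt_pct(row$conf.low), fmt_pct(row$conf.high)))
  }
  invisible(x)
}

#' @export
tidy.concordance_report <- function(x, ...) {
  x$estimates
}

#' @export
glance.concordance_report <- function(x, ...) {
  wide <- tibble::new_tibble(list(), nrow = 1)
  for (i in seq_len(nrow(x$estimates))) {
    row <- x$estimates[i, ]
    wide[[row$statistic]] <- row$estimate
    wide[[paste0(row$statistic, "_low")]] <- row$conf.low
    wide[[paste0(row$statistic, "_high")]] <- row$conf.high
  }
  dplyr::bind_cols(
    tibble::tibble(
      a = x$table$a, b = x$table$b, c = x$table$c, d = x$table$d,
      n = x$n, n_excluded = nrow(x$table$excluded)
    ),
    wide
  )
}
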