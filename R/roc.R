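#' @noRd
as_positive <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) return(labels != 0)
  if (!all(labels %in% c(ref_positive, ref_negative))) {
    abort("labels must be logical or POSITIVE/NEGATIVE (HIGH/LOW) statuses")
  }
  labels %in% ref_positive
}

#' ROC curve and AUC for delta-Ct scores against a binary reference
#'
#' Sweeps the call threshold over the observed delta-Ct values (a sample is
#' called positive when its score is at or above the threshold, matching the
#' call engine's boundary rule) and traces true- and false-positive rates.
#' The AUC is computed by the trapezoidal rule, which on this construction
#' equals the Mann-Whitney estimate: the probability that a random positive
#' scores above a random negative, counting ties one half.
#'
#' @param scores Numeric scores (delta-Ct; higher = more positive).
#' @param labels Reference labels: logical, or POSITIVE/NEGATIVE (HIGH/LOW).
#' @return An object of class `strat4_roc` with elements `points` (tibble of
#'   `threshold`, `tpr`, `fpr`), `auc`, `n_pos`, `n_neg`. `tidy()` returns the
#'   points, `glance()` a one-row AUC summary, `autoplot()` the curve.
#' @examples
#' r <- roc_dct(c(-2, -1, 0, 1), c(FALSE, TRUE, FALSE, TRUE))
#' r$auc  # 0.75
#' @export
roc_dct <- function(scores, labels) {
  pos <- as_positive(labels)
  keep <- !is.na(scores) & !is.na(pos)
  scores <- scores[keep]
  pos <- pos[keep]
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) {
    abort("both classes must be present: AUC is undefined otherwise")
  }
  u <- sort(unique(scores), decreasing = TRUE)
  idx <- match(scores, u)
  counts <- tabulate(idx, nbins = length(u))
  pos_counts <- tabulate(idx[pos], nbins = length(u))
  tp <- cumsum(pos_counts)
  fp <- cumsum(counts - pos_counts)
  points <- tibble::tibble(
    threshold = c(Inf, u),
    tpr = c(0, tp / n_pos),
    fpr = c(0, fp / n_neg)
  )
  auc <- sum(diff(points$fpr) * (utils::head(points$tpr, -1) + utils::tail(points$tpr, -1)) / 2)
  structure(
    list(points = points, auc = auc, n_pos = n_pos, n_neg = n_neg),
    class = "strat4_roc"
  )
}

#' @export
print.strat4_roc <- function(x, ...) {
  cat(sprintf("<strat4_roc> AUC = %.3f (%d positive, %d negative, %d thresholds)\n",
              x$auc, x$n_pos, x$n_neg, nrow(x$points) - 1))
  invisible(x)
}

#' @export
tidy.strat4_roc <- function(x, ...) x$points

#' @export
glance.strat4_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' @param object A `strat4_roc`.
#' @param ... Unused.
#' @rdname roc_dct
#' @export
autoplot.strat4_roc <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate (1 - NPA)",
      y = "True positive rate (PPA)",
      title = sprintf("AUC = %.3f", object$auc)
    ) +
    ggplot2::theme_minimal()
}

#' Optimal delta-Ct cutoff by maximal overall agreement
#'
#' Searches candidate cutoffs — the midpoints between adjacent distinct
#' scores, plus sentinels at plus and minus infinity — for the one maximising
#' overall percent agreement with the reference labels (positive call =
#' score at or above the cutoff). Ties are broken toward the cutoff with the
#' higher positive agreement (favouring sensitivity), then toward the
#' smallest cutoff.
#'
#' @inheritParams roc_dct
#' @return A one-row tibble: `cutoff`, `opa`, `ppa`, `npa`.
#' @examples
#' optimize_cutoff(c(-3, -2, 0, 1), c(FALSE, FALSE, TRUE, TRUE))  # cutoff -1, OPA 1
#' @export
optimize_cutoff <- function(scores, labels) {
  pos <- as_positive(labels)
  keep <- !is.na(scores) & !is.na(pos)
  scores <- scores[keep]
  pos <- pos[keep]
  if (sum(pos) == 0 || sum(!pos) == 0) {
    abort("both classes must be present to optimise a cutoff")
  }
  # sweep in one pass over the sorted scores: with the k smallest observations
  # predicted negative, agreement counts follow from cumulative positives
  ord <- order(scores)
  s <- scores[ord]
  p <- pos[ord]
  n <- length(s)
  n_pos <- sum(p)
  n_neg <- n - n_pos
  cum_pos <- c(0, cumsum(p))
  # candidate boundaries: before everything, between distinct values, after all
  ks <- c(0, which(diff(s) > 0), n)
  cutoffs <- c(-Inf, (s[ks[ks > 0 & ks < n]] + s[ks[ks > 0 & ks < n] + 1]) / 2, Inf)
  opa <- (ks - cum_pos[ks + 1] + n_pos - cum_pos[ks + 1]) / n
  ppa <- (n_pos - cum_pos[ks + 1]) / n_pos
  npa <- (ks - cum_pos[ks + 1]) / n_neg
  # PPA is nonincreasing along the sweep and cutoffs increase, so the first
  # OPA maximiser also wins both tie-breaks (highest PPA, smallest cutoff)
  i <- which.max(opa)
  tibble::tibble(cutoff = cutoffs[i], opa = opa[i], ppa = ppa[i], npa = npa[i])
}
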