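#' Tolerance-window one-to-one peak matching
#'
#' Pairs detected and reference peaks greedily over ascending absolute time
#' difference; a pair matches only when it lies within the tolerance
#' (default +/- 50 ms, a window wide enough to enclose a mid-gestation
#' fetal QRS complex), and each peak can be used at most once. Unmatched
#' detected peaks are false positives, unmatched reference peaks false
#' negatives.
#'
#' @param detected,reference [peak_annotations()] objects at the same
#'   sampling rate.
#' @param tolerance_ms Matching tolerance in milliseconds (`|dt| <=`
#'   tolerance).
#' @return Named integer vector `c(TP, FP, FN)`.
#' @export
match_peaks <- function(detected, reference, tolerance_ms = 50) {
  stopifnot(inherits(detected, "peak_annotations"),
            inherits(reference, "peak_annotations"),
            tolerance_ms > 0)
  if (detected$fs != reference$fs) {
    stop("detected and reference annotations use different sampling rates",
         call. = FALSE)
  }
  tol <- tolerance_ms * detected$fs / 1000
  d <- detected$indices
  r <- reference$indices
  if (length(d) == 0 || length(r) == 0) {
    return(c(TP = 0L, FP = length(d), FN = length(r)))
  }
  pairs <- expand.grid(di = seq_along(d), ri = seq_along(r))
  pairs$dt <- abs(d[pairs$di] - r[pairs$ri])
  pairs <- pairs[pairs$dt <= tol, , drop = FALSE]
  pairs <- pairs[order(pairs$dt, pairs$ri, pairs$di), , drop = FALSE]
  used_d <- logical(length(d))
  used_r <- logical(length(r))
  tp <- 0L
  for (k in seq_len(nrow(pairs))) {
    di <- pairs$di[k]; ri <- pairs$ri[k]
    if (!used_d[di] && !used_r[ri]) {
      used_d[di] <- used_r[ri] <- TRUE
      tp <- tp + 1L
    }
  }
  c(TP = tp, FP = sum(!used_d), FN = sum(!used_r))
}

#' Fetal QRS detection metrics
#'
#' The four standard detection figures of merit:
#' `ACCdet = TP / (TP + FP + FN)`, `TPRdet = TP / (TP + FN)`,
#' `PPVdet = TP / (TP + FP)`, `F1det = 2 PPV TPR / (PPV + TPR)`.
#' A zero denominator yields `NA`, excluded from aggregation.
#'
#' @param counts Named vector with `TP`, `FP`, `FN` (as from
#'   [match_peaks()]).
#' @return An object of class `detection_score`: named vector with the
#'   counts and the four metrics.
#' @export
detection_metrics <- function(counts) {
  tp <- as.numeric(counts[["TP"]])
  fp <- as.numeric(counts[["FP"]])
  fn <- as.numeric(counts[["FN"]])
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  acc <- if (tp + fp + fn > 0) tp / (tp + fp + fn) else NA_real_
  tpr <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(tpr) && !is.na(ppv) && tpr + ppv > 0) {
    2 * ppv * tpr / (ppv + tpr)
  } else {
    NA_real_
  }
  structure(c(TP = tp, FP = fp, FN = fn,
              ACCdet = acc, TPRdet = tpr, PPVdet = ppv, F1det = f1),
            class = "detection_score")
}

#' Compare detection performance across channel-selection conditions
#'
#' Given one metric value per recording for each condition (e.g. all
#' channels vs selected channels), runs the Kruskal--Wallis test across all
#' conditions and paired Wilcoxon signed-rank tests on every condition
#' pair, Bonferroni-correcting the pairwise family. All-tied comparisons
#' are reported with p = 1.
#'
#' @param scores Numeric matrix or data frame, recordings in rows, one
#'   column per condition (named).
#' @param alpha Significance level.
#' @return An object of class `comparison_report`: list with
#'   `kruskal_statistic`, `kruskal_p`, a data frame `pairwise` (pair, raw
#'   and Bonferroni-corrected p, significant flag) and `alpha`.
#' @export
compare_conditions <- function(scores, alpha = 0.05) {
  scores <- as.matrix(scores)
  stopifnot(nrow(scores) >= 6, ncol(scores) >= 2)
  if (is.null(colnames(scores))) {
    colnames(scores) <- paste0("cond", seq_len(ncol(scores)))
  }
  complete <- stats::complete.cases(scores)
  scores <- scores[complete, , drop = FALSE]

  if (all(scores == scores[1, 1])) {
    kw_stat <- 0; kw_p <- 1
  } else {
    kw <- kruskal.test(split(as.numeric(scores),
                             rep(colnames(scores), each = nrow(scores))))
    kw_stat <- unname(kw$statistic); kw_p <- kw$p.value
  }

  pairs <- utils::combn(colnames(scores), 2)
  n_cmp <- ncol(pairs)
  raw_p <- vapply(seq_len(n_cmp), function(k) {
    a <- scores[, pairs[1, k]]; b <- scores[, pairs[2, k]]
    if (all(a == b)) return(1)
    suppressWarnings(wilcox.test(a, b, paired = TRUE)$p.value)
  }, numeric(1))
  corrected <- pmin(1, raw_p * n_cmp)
  structure(list(
    kruskal_statistic = kw_stat,
    kruskal_p = kw_p,
    pairwise = data.frame(
      condition_a = pairs[1, ], condition_b = pairs[2, ],
      p_raw = raw_p, p_corrected = corrected,
      significant = corrected < alpha),
    alpha = alpha,
    n_recordings = nrow(scores)),
    class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> %d recordings, Kruskal-Wallis p = %.3g\n",
              x$n_recordings, x$kruskal_p))
  print(x$pairwise)
  invisible(x)
}
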