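#' Plug-in mutual information between a feature and a discrete variable
#'
#' The feature is discretised into `n_bins` equal-frequency bins (quantile
#' cuts; duplicated quantiles collapse, so a constant feature has a single
#' bin and zero information). The plug-in estimate is returned in bits.
#'
#' @param x Numeric feature vector.
#' @param y Vector of labels (or another discretised feature) of the same
#'   length, at least 10 samples.
#' @param n_bins Number of equal-frequency bins for `x`.
#' @return Non-negative scalar, bits.
#' @export
mutual_information <- function(x, y, n_bins = 10L) {
  stopifnot(length(x) == length(y), length(x) >= 10)
  xb <- discretize_ef(x, n_bins)
  discrete_mi(xb, y)
}

# Equal-frequency binning; returns an integer factor-like vector.
discretize_ef <- function(x, n_bins = 10L) {
  br <- unique(quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                        names = FALSE, type = 7))
  if (length(br) < 2) return(rep(1L, length(x)))
  findInterval(x, br, rightmost.closed = TRUE, all.inside = TRUE)
}

# Plug-in MI (bits) between two discrete vectors.
discrete_mi <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  if (n == 0) return(0)
  pij <- tab / n
  pi_ <- rowSums(pij); p_j <- colSums(pij)
  pos <- pij > 0
  sum(pij[pos] * log2(pij[pos] / (pi_[row(pij)[pos]] * p_j[col(pij)[pos]])))
}

#' Greedy mRMR ranking of a feature table
#'
#' Minimum-redundancy maximum-relevance with the difference (MID) criterion:
#' the first feature maximises the mutual information with the label; each
#' subsequent pick maximises `MI(f, y) - mean(MI(f, s))` over the already
#' selected set `s`. A feature's raw relevance score is its criterion value
#' at selection time, floored at 0. Ties are broken by the canonical feature
#' order (column order of `x`).
#'
#' @param x Numeric matrix or data frame of features (columns named).
#' @param y Binary label vector; both classes must be present.
#' @param n_bins Equal-frequency bins for the mutual-information estimates.
#' @return Named numeric vector of raw scores for all features, in the
#'   greedy selection order.
#' @export
mrmr_rank <- function(x, y, n_bins = 10L) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("at least two features required", call. = FALSE)
  if (length(unique(y)) < 2) {
    stop("both classes must be present in the labels", call. = FALSE)
  }
  p <- ncol(x)
  nms <- colnames(x)
  if (is.null(nms)) nms <- paste0("f", seq_len(p))
  binned <- lapply(seq_len(p), function(j) discretize_ef(x[, j], n_bins))
  rel <- vapply(binned, function(b) discrete_mi(b, y), numeric(1))

  red <- matrix(NA_real_, p, p)        # pairwise MI cache
  pair_mi <- function(i, j) {
    if (is.na(red[i, j])) {
      red[i, j] <<- red[j, i] <<- discrete_mi(binned[[i]], binned[[j]])
    }
    red[i, j]
  }

  selected <- integer(0)
  scores <- numeric(0)
  remaining <- seq_len(p)
  for (k in seq_len(p)) {
    crit <- vapply(remaining, function(j) {
      if (length(selected) == 0) rel[j]
      else rel[j] - mean(vapply(selected, function(s) pair_mi(j, s),
                                numeric(1)))
    }, numeric(1))
    # ties (within float noise) break by canonical column order
    m <- max(crit)
    best <- remaining[crit >= m - 1e-9 * max(1, abs(m))][1]
    scores <- c(scores, max(crit[which(remaining == best)], 0))
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
  }
  stats::setNames(scores, nms[selected])
}

#' Aggregate per-partition relevance scores into one ranking
#'
#' Each partition's raw score vector is min-max normalised to \[0, 1\] (a
#' degenerate all-equal partition contributes zeros), the normalised vectors
#' are summed feature-wise across partitions, and the features are sorted by
#' descending aggregated relevance.
#'
#' @param per_partition_scores List of named numeric vectors, one per
#'   cross-validation partition, all covering the same feature set.
#' @return An object of class `relevance_ranking`: list with
#'   `feature_names` (descending relevance), `aggregated_scores` (same
#'   order) and `n_partitions`.
#' @export
aggregate_relevance <- function(per_partition_scores) {
  stopifnot(is.list(per_partition_scores), length(per_partition_scores) >= 1)
  nms <- sort(names(per_partition_scores[[1]]))
  acc <- stats::setNames(numeric(length(nms)), nms)
  for (v in per_partition_scores) {
    if (!setequal(names(v), nms)) {
      stop("every partition must score the same feature set", call. = FALSE)
    }
    v <- v[nms]
    rng <- range(v)
    norm <- if (rng[2] > rng[1]) (v - rng[1]) / (rng[2] - rng[1])
            else v * 0
    acc <- acc + norm
  }
  ord <- order(-acc, match(names(acc), names(per_partition_scores[[1]])))
  structure(list(feature_names = names(acc)[ord],
                 aggregated_scores = unname(acc[ord]),
                 n_partitions = length(per_partition_scores)),
            class = "relevance_ranking")
}

#' @export
print.relevance_ranking <- function(x, ...) {
  cat(sprintf("<relevance_ranking> %d features over %d partitions\n",
              length(x$feature_names), x$n_partitions))
  print(stats::setNames(round(x$aggregated_scores, 3), x$feature_names))
  invisible(x)
}

#' Select the smallest feature prefix reaching a relevance fraction
#'
#' Walks the descending-relevance ordering and returns the smallest prefix
#' whose cumulative aggregated score reaches `fraction` of the total.
#'
#' @param ranking A [aggregate_relevance()] result.
#' @param fraction Target fraction of total relevance in (0, 1\].
#' @return Character vector of selected feature names (a prefix of
#'   `ranking$feature_names`).
#' @export
select_features <- function(ranking, fraction = 0.8) {
  stopifnot(inherits(ranking, "relevance_ranking"),
            fraction > 0, fraction <= 1)
  total <- sum(ranking$aggregated_scores)
  if (total == 0) return(ranking$feature_names[1])
  k <- which(cumsum(ranking$aggregated_scores) >= fraction * total - 1e-12)[1]
  ranking$feature_names[seq_len(k)]
}

#' mRMR relevance aggregated over the cross-validation training splits
#'
#' Reproduces the ranking protocol of the channel-selection pipeline: for
#' every training split of the repeated stratified k-fold scheme (10 x 10 by
#' default, i.e. 100 partitions) the greedy mRMR scores are computed on the
#' training 9/10 of the data, normalised per partition, and aggregated with
#' [aggregate_relevance()].
#'
#' @param table A labelled feature table (see [sqi_feature_table()]).
#' @param scheme A [cv_scheme()].
#' @param n_bins Bins for the mutual-information estimates.
#' @return A `relevance_ranking`.
#' @export
rank_features_cv <- function(table, scheme = cv_scheme(), n_bins = 10L) {
  x <- as.matrix(table[, sqi_feature_names()])
  y <- table$label
  per_part <- list()
  for (r in seq_len(scheme$n_repeats)) {
    folds <- stratified_folds(y, scheme$n_folds, seed = scheme$seed + r)
    for (f in seq_len(scheme$n_folds)) {
      tr <- folds != f
      per_part[[length(per_part) + 1L]] <- mrmr_rank(x[tr, , drop = FALSE],
                                                     y[tr], n_bins = n_bins)
    }
  }
  aggregate_relevance(per_part)
}
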