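#' Bagged-tree ensemble parameters
#'
#' Defaults mirror a stock bagged-tree configuration: 100 bootstrap learning
#' cycles with at most ten decision splits per tree. `features_per_split`
#' chooses between random-subspace bagging (`"sqrt"`, the square root of the
#' feature count per split) and plain bagging over all features (`"all"`).
#'
#' @param n_learners Number of trees.
#' @param max_splits_per_tree Maximum internal (decision) nodes per tree.
#' @param features_per_split `"sqrt"` or `"all"`.
#' @param seed Integer seed; identical data, parameters and seed give
#'   identical models and predictions.
#' @return An object of class `ensemble_params`.
#' @export
ensemble_params <- function(n_learners = 100L, max_splits_per_tree = 10L,
                            features_per_split = c("sqrt", "all"),
                            seed = 1L) {
  stopifnot(n_learners >= 1, max_splits_per_tree >= 1)
  features_per_split <- match.arg(features_per_split)
  structure(list(n_learners = as.integer(n_learners),
                 max_splits_per_tree = as.integer(max_splits_per_tree),
                 features_per_split = features_per_split,
                 seed = as.integer(seed)),
            class = "ensemble_params")
}

#' Repeated stratified cross-validation scheme
#'
#' @param n_folds Number of folds (default 10).
#' @param n_repeats Number of independent fold partitions (default 10).
#' @param seed Integer seed for the partitioning.
#' @return An object of class `cv_scheme`.
#' @export
cv_scheme <- function(n_folds = 10L, n_repeats = 10L, seed = 1L) {
  stopifnot(n_folds >= 2, n_repeats >= 1)
  structure(list(n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats),
                 seed = as.integer(seed)),
            class = "cv_scheme")
}

# Stratified fold assignment: within each class, shuffle and deal folds
# round-robin, so per-fold class counts differ by at most one.
stratified_folds <- function(y, n_folds, seed) {
  set.seed(seed)
  folds <- integer(length(y))
  for (cl in unique(y)) {
    rows <- which(y == cl)
    folds[rows[sample.int(length(rows))]] <-
      rep_len(seq_len(n_folds), length(rows))
  }
  folds
}

#' Train the bagged decision-tree channel classifier
#'
#' Fits an ensemble of CART trees (Gini impurity, axis-aligned splits) on
#' bootstrap resamples of the labelled feature table, each tree grown to at
#' most `max_splits_per_tree` internal nodes. The positive class is
#' `informative`.
#'
#' @param table Labelled feature table: data frame with the
#'   [sqi_feature_names()] columns, a `label` factor and (optionally) a
#'   `degenerate` logical column.
#' @param params An [ensemble_params()].
#' @param feature_subset Optional character vector restricting the features
#'   used (e.g. from [select_features()]).
#' @return An object of class `sqa_model`.
#' @export
train_sqa_classifier <- function(table, params = ensemble_params(),
                                 feature_subset = NULL) {
  stopifnot(is.data.frame(table), nrow(table) > 0,
            inherits(params, "ensemble_params"))
  features <- feature_subset %||% sqi_feature_names()
  if (!all(features %in% names(table))) {
    stop("feature subset not present in the table", call. = FALSE)
  }
  y <- droplevels_to_binary(table$label)
  if (nlevels(y) < 2 || any(table(y) == 0)) {
    stop("both classes must be present for training", call. = FALSE)
  }
  x <- as.matrix(table[, features, drop = FALSE])
  mtry <- if (params$features_per_split == "sqrt") {
    max(1L, floor(sqrt(length(features))))
  } else {
    length(features)
  }
  set.seed(params$seed)
  forest <- randomForest::randomForest(
    x = x, y = y,
    ntree = params$n_learners,
    mtry = mtry,
    replace = TRUE,
    maxnodes = params$max_splits_per_tree + 1L)
  structure(list(forest = forest, features = features, params = params),
            class = "sqa_model")
}

droplevels_to_binary <- function(label) {
  factor(as.character(label), levels = c("non_informative", "informative"))
}

#' @export
print.sqa_model <- function(x, ...) {
  cat(sprintf("<sqa_model> %d bagged trees, <=%d splits, features: %s\n",
              x$params$n_learners, x$params$max_splits_per_tree,
              paste(x$features, collapse = ", ")))
  invisible(x)
}

#' Predict channel quality labels for feature rows
#'
#' The score is the fraction of trees voting `informative`; a row is labelled
#' informative only with a strict majority (a 0.5 tie is conservatively
#' non-informative). Rows flagged degenerate (zero-variance segments) are
#' non-informative by construction, regardless of the trees.
#'
#' @param object An `sqa_model`.
#' @param newdata Data frame (or matrix) with the model's feature columns;
#'   an optional logical `degenerate` column forces non-informative rows.
#' @param ... Unused.
#' @return Data frame with `label` (factor) and `score` in \[0, 1\].
#' @export
predict.sqa_model <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  if (!all(object$features %in% names(newdata))) {
    stop("missing feature columns in `newdata`", call. = FALSE)
  }
  x <- as.matrix(newdata[, object$features, drop = FALSE])
  votes <- predict(object$forest, x, type = "vote", norm.votes = TRUE)
  score <- as.numeric(votes[, "informative"])
  if ("degenerate" %in% names(newdata)) {
    score[as.logical(newdata$degenerate)] <- 0
  }
  data.frame(
    label = factor(ifelse(score > 0.5, "informative", "non_informative"),
                   levels = c("non_informative", "informative")),
    score = score)
}

#' Confusion-count classification metrics
#'
#' `Acc`, `TPR` (sensitivity), `TNR` (specificity), `PPV` (precision) and
#' `F1` from the four confusion counts; any metric with a zero denominator
#' is returned as `NA` and excluded from downstream medians.
#'
#' @param tp,fp,tn,fn Non-negative counts (positive class = informative).
#' @return Named numeric vector `c(Acc, TPR, TNR, PPV, F1)`.
#' @export
classification_metrics <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0, tp + fp + tn + fn > 0)
  acc <- (tp + tn) / (tp + fp + tn + fn)
  tpr <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  tnr <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(tpr) && !is.na(ppv) && tpr + ppv > 0) {
    2 * ppv * tpr / (ppv + tpr)
  } else {
    NA_real_
  }
  c(Acc = acc, TPR = tpr, TNR = tnr, PPV = ppv, F1 = f1)
}

#' Repeated stratified cross-validation of the channel classifier
#'
#' For each repeat a fresh stratified fold partition is drawn; each fold is
#' held out once while the ensemble is trained on the remainder. Returns all
#' `n_repeats * n_folds` metric tuples plus their medians and quartiles
#' (undefined metrics excluded).
#'
#' @param table Labelled feature table (see [train_sqa_classifier()]).
#' @param params An [ensemble_params()].
#' @param scheme A [cv_scheme()].
#' @param feature_subset Optional feature subset.
#' @return An object of class `sqa_cv`: list with `metrics` (data frame with
#'   `repeat_`, `fold` and the five metrics) and `summary` (median, q25, q75
#'   per metric).
#' @export
cross_validate <- function(table, params = ensemble_params(),
                           scheme = cv_scheme(), feature_subset = NULL) {
  y <- droplevels_to_binary(table$label)
  if (any(table(y) < scheme$n_folds)) {
    stop("each class needs at least one sample per fold", call. = FALSE)
  }
  rows <- list()
  for (r in seq_len(scheme$n_repeats)) {
    folds <- stratified_folds(y, scheme$n_folds, seed = scheme$seed + r)
    for (f in seq_len(scheme$n_folds)) {
      tr <- folds != f
      fit_params <- params
      fit_params$seed <- params$seed + 1000L * r + f
      model <- train_sqa_classifier(table[tr, , drop = FALSE], fit_params,
                                    feature_subset)
      pred <- predict(model, table[!tr, , drop = FALSE])
      truth <- y[!tr]
      tp <- sum(pred$label == "informative" & truth == "informative")
      fp <- sum(pred$label == "informative" & truth == "non_informative")
      tn <- sum(pred$label == "non_informative" & truth == "non_informative")
      fn <- sum(pred$label == "non_informative" & truth == "informative")
      rows[[length(rows) + 1L]] <-
        c(repeat_ = r, fold = f, classification_metrics(tp, fp, tn, fn))
    }
  }
  metrics <- as.data.frame(do.call(rbind, rows))
  metric_names <- c("Acc", "TPR", "TNR", "PPV", "F1")
  summary <- t(vapply(metric_names, function(m) {
    v <- metrics[[m]]
    quantile(v[!is.na(v)], c(0.5, 0.25, 0.75), names = FALSE)
  }, numeric(3)))
  colnames(summary) <- c("median", "q25", "q75")
  structure(list(metrics = metrics, summary = as.data.frame(summary)),
            class = "sqa_cv")
}

#' @export
print.sqa_cv <- function(x, ...) {
  cat(sprintf("<sqa_cv> %d partitions\n", nrow(x$metrics)))
  print(round(x$summary, 3))
  invisible(x)
}

#' Select the informative abdominal channels of a recording
#'
#' Runs the full quality pipeline on a raw recording: preprocess with the
#' named preset, segment each abdominal channel into 5-s windows, compute
#' the sixteen quality indexes per segment, classify every segment, and keep
#' the channels for which a strict majority of segments is predicted
#' informative. An empty selection is a valid outcome.
#'
#' @param model An `sqa_model`.
#' @param rec An [mc_recording()] at least 5 s long with abdominal channels.
#' @param preset Preprocessing preset, see [preprocess_preset()].
#' @return Integer vector of selected abdominal channel indices (1-based,
#'   into the recording's channel order), with attribute `vote_fraction`
#'   giving the informative-segment fraction for every abdominal channel.
#' @export
select_channels <- function(model, rec, preset = "train") {
  stopifnot(inherits(model, "sqa_model"), inherits(rec, "mc_recording"))
  if (ncol(rec$samples) < 5 * rec$fs) {
    stop("recording must be at least 5 s long", call. = FALSE)
  }
  abd <- which(rec$channel_roles == "abdominal")
  if (length(abd) == 0) stop("no abdominal channels", call. = FALSE)
  tbl <- sqi_feature_table(rec, preset = preset)
  pred <- predict(model, tbl)
  frac <- vapply(abd, function(ch) {
    sel <- tbl$channel == ch
    mean(pred$label[sel] == "informative")
  }, numeric(1))
  names(frac) <- rec$channel_names[abd]
  structure(abd[frac > 0.5], vote_fraction = frac)
}
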