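test_that("confusion metrics follow the standard formulas", {
  m <- classification_metrics(tp = 8, fp = 2, tn = 7, fn = 1)
  expect_equal(unname(m["Acc"]), 15 / 18)
  expect_equal(unname(m["TPR"]), 8 / 9)
  expect_equal(unname(m["TNR"]), 7 / 9)
  expect_equal(unname(m["PPV"]), 0.8)
  expect_equal(unname(m["F1"]), 2 * 0.8 * (8 / 9) / (0.8 + 8 / 9))
  perfect <- classification_metrics(10, 0, 10, 0)
  expect_true(all(perfect == 1))
  expect_true(is.na(classification_metrics(0, 0, 5, 3)["PPV"]))
})

test_that("a perfectly separating feature gives training accuracy 1", {
  tbl <- make_separable_table(200, seed = 1, margin = 4)
  model <- train_sqa_classifier(tbl, ensemble_params(seed = 2))
  pred <- predict(model, tbl)
  expect_equal(mean(pred$label == tbl$label), 1)
})

test_that("training and prediction are deterministic given the seed", {
  tbl <- make_separable_table(300, seed = 3, margin = 1)
  m1 <- train_sqa_classifier(tbl, ensemble_params(seed = 5))
  m2 <- train_sqa_classifier(tbl, ensemble_params(seed = 5))
  expect_identical(predict(m1, tbl), predict(m2, tbl))
})

test_that("degenerate rows and vote ties fall to non-informative", {
  tbl <- make_separable_table(200, seed = 4, margin = 4)
  model <- train_sqa_classifier(tbl, ensemble_params(seed = 1))
  row <- tbl[tbl$label == "informative", ][1, ]
  row$degenerate <- TRUE
  pred <- predict(model, row)
  expect_identical(as.character(pred$label), "non_informative")
  expect_equal(pred$score, 0)
  # tie handling is a documented contract of the score threshold
  expect_identical(
    as.character(predict(model, tbl)$label[predict(model, tbl)$score == 0.5]),
    rep("non_informative", sum(predict(model, tbl)$score == 0.5)))
})

test_that("stratified folds balance size and class ratio", {
  y <- factor(rep(c("non_informative", "informative"), c(140, 60)))
  folds <- fecgsqa:::stratified_folds(y, 10, seed = 8)
  sizes <- table(folds)
  expect_lte(max(sizes) - min(sizes), 1)
  per_fold_pos <- vapply(1:10, function(f) {
    sum(y[folds == f] == "informative")
  }, numeric(1))
  expect_lte(max(per_fold_pos) - min(per_fold_pos), 1)
})

test_that("cross-validation separates the separable and not the shuffled", {
  tbl <- make_separable_table(400, seed = 6, margin = 4)
  cv <- cross_validate(tbl, ensemble_params(n_learners = 50, seed = 1),
                       cv_scheme(n_folds = 10, n_repeats = 2, seed = 3))
  expect_equal(nrow(cv$metrics), 20)
  expect_gte(cv$summary["Acc", "median"], 0.99)
  expect_true(all(cv$metrics$F1 >= 0 & cv$metrics$F1 <= 1, na.rm = TRUE))
  # determinism of the whole CV result
  cv2 <- cross_validate(tbl, ensemble_params(n_learners = 50, seed = 1),
                        cv_scheme(n_folds = 10, n_repeats = 2, seed = 3))
  expect_identical(cv, cv2)
})

test_that("channel selection recovers truly informative channels", {
  tr <- build_training_set(n_recordings = 4, duration = 20, seed = 1)
  model <- train_sqa_classifier(tr, ensemble_params(seed = 7))
  sim <- generate_recording(study_recording_config(501, duration = 20))
  truth_pos <- which(sim$truth$true_fetal_snr > 7)
  truth_neg <- which(sim$truth$true_fetal_snr < 0)
  sel <- select_channels(model, sim$recording, preset = "train")
  expect_true(all(truth_pos %in% sel))
  expect_false(any(truth_neg %in% sel))
  # vote fraction rises with true channel SNR on graded fetal amplitudes
  graded <- generate_recording(synth_config(
    n_abdominal_channels = 24, duration = 40,
    fetal_amp_per_channel = seq(8, 60, length.out = 24),
    maternal_gain_per_channel = seq(0.45, 0.1, length.out = 24),
    noise_std = 2, seed = 77))
  sel_g <- select_channels(model, graded$recording, preset = "train")
  rho <- suppressWarnings(cor(attr(sel_g, "vote_fraction"),
                              graded$truth$true_fetal_snr,
                              method = "spearman"))
  expect_gt(rho, 0.8)
  # recordings shorter than one segment are rejected
  short <- sim$recording
  short$samples <- short$samples[, 1:1000]
  expect_error(select_channels(model, short), "5 s")
})

test_that("all-zero channels are never selected", {
  tr <- make_separable_table(200, seed = 2, margin = 4)
  model <- train_sqa_classifier(tr, ensemble_params(seed = 3))
  rec <- mc_recording(matrix(0, 2, 5000), fs = 500,
                      channel_roles = c("abdominal", "abdominal"))
  sel <- select_channels(model, rec, preset = NULL)
  expect_length(sel, 0)
})
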