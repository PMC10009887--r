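test_that("mutual information matches its analytic anchors", {
  set.seed(1)
  x <- rnorm(2000)
  y <- as.integer(x > median(x))
  expect_lt(abs(mutual_information(x, y) - 1), 0.05)
  # independence: MI near zero across seeds
  mis <- vapply(1:50, function(s) {
    set.seed(s)
    mutual_information(rnorm(2000), sample(0:1, 2000, replace = TRUE))
  }, numeric(1))
  expect_true(all(mis < 0.02))
  expect_equal(mutual_information(rep(1, 100), sample(0:1, 100, TRUE)), 0)
})

test_that("greedy ranking puts signal first and redundancy last", {
  set.seed(2)
  n <- 500
  y <- rep(0:1, n / 2)
  f1 <- y + rnorm(n, sd = 0.05)
  x <- cbind(f1 = f1, f2 = rnorm(n))
  scores <- mrmr_rank(x, y)
  expect_identical(names(scores)[1], "f1")
  # exact copy of f1 scores ~0 (fully redundant)
  x3 <- cbind(f1 = f1, f2 = f1, f3 = rnorm(n))
  s3 <- mrmr_rank(x3, y)
  expect_lt(s3[["f2"]], 0.05)
  expect_error(mrmr_rank(x, rep(1, n)), "both classes")
})

test_that("greedy order equals brute-force recomputation on small tables", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 120
    p <- sample(3:6, 1)
    y <- rep(0:1, length.out = n)
    x <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("f", 1:p)))
    x[, 1] <- x[, 1] + y
    if (p >= 4) x[, 4] <- x[, 1] + rnorm(n, sd = 0.2)
    got <- names(mrmr_rank(x, y))
    want <- oracle_mrmr_order(x, y)
    expect_identical(got, want)
  }
})

test_that("aggregation normalises per partition and sums across them", {
  s1 <- c(a = 2, b = 1, c = 0)
  # identical partitions: ordering equals single-partition ordering
  agg2 <- aggregate_relevance(list(s1, s1))
  agg1 <- aggregate_relevance(list(s1))
  expect_identical(agg2$feature_names, agg1$feature_names)
  expect_equal(agg2$aggregated_scores, 2 * agg1$aggregated_scores)
  expect_equal(agg1$aggregated_scores, c(1, 0.5, 0))
  # degenerate all-equal partition contributes zeros
  agg <- aggregate_relevance(list(s1, c(a = 1, b = 1, c = 1)))
  expect_equal(agg$aggregated_scores, c(1, 0.5, 0))
})

test_that("column permutation permutes the ranking identically", {
  set.seed(3)
  n <- 300
  y <- rep(0:1, n / 2)
  x <- matrix(rnorm(n * 5), n, 5,
              dimnames = list(NULL, paste0("f", 1:5)))
  x[, 2] <- x[, 2] + 2 * y
  x[, 5] <- x[, 5] + y
  base <- mrmr_rank(x, y)
  perm <- c(4, 2, 5, 1, 3)
  permuted <- mrmr_rank(x[, perm], y)
  expect_identical(sort(names(base)), sort(names(permuted)))
  expect_equal(unname(permuted[names(base)]), unname(base))
})

test_that("the selected prefix is the smallest reaching the fraction", {
  r <- structure(list(feature_names = c("a", "b", "c"),
                      aggregated_scores = c(0.5, 0.3, 0.2),
                      n_partitions = 1L),
                 class = "relevance_ranking")
  expect_identical(select_features(r, 0.8), c("a", "b"))
  expect_identical(select_features(r, 1.0), c("a", "b", "c"))
  r2 <- structure(list(feature_names = c("a", "b", "c"),
                       aggregated_scores = c(9, 0.6, 0.4),
                       n_partitions = 1L),
                  class = "relevance_ranking")
  expect_identical(select_features(r2, 0.8), "a")
})

test_that("label shuffling collapses the aggregated relevance", {
  tbl <- make_separable_table(400, seed = 5)
  x <- as.matrix(tbl[, sqi_feature_names()])
  y <- tbl$label
  parts <- lapply(1:5, function(s) {
    set.seed(s)
    rows <- sample(nrow(x), 300)
    mrmr_rank(x[rows, ], y[rows])
  })
  agg <- aggregate_relevance(parts)
  set.seed(99)
  parts_shuf <- lapply(1:5, function(s) {
    set.seed(s)
    rows <- sample(nrow(x), 300)
    mrmr_rank(x[rows, ], sample(as.character(y[rows])))
  })
  agg_shuf <- aggregate_relevance(parts_shuf)
  expect_lt(mean(agg_shuf$aggregated_scores),
            0.25 * max(agg$aggregated_scores))
})
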