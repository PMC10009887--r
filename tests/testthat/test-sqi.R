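fs <- 500
t5 <- (0:(5 * fs - 1)) / fs

test_that("Welch PSD localises tones and satisfies Parseval for noise", {
  psd <- estimate_psd(sin(2 * pi * 15 * t5), fs)
  expect_lte(abs(psd$freqs[which.max(psd$power)] - 15), 1)
  # integrated power ~ variance for white noise (Monte Carlo)
  set.seed(42)
  ratio <- replicate(50, {
    x <- rnorm(5 * fs, sd = 2)
    psd <- estimate_psd(x, fs)
    sum(psd$power) * (psd$freqs[2] - psd$freqs[1]) / 4
  })
  expect_lt(abs(mean(ratio) - 1), 0.1)
  zero <- estimate_psd(numeric(5 * fs), fs)
  expect_true(all(zero$power == 0))
})

test_that("band power averages the requested closed band", {
  psd <- estimate_psd(sin(2 * pi * 15 * t5), fs)
  expect_gt(band_power(psd, 10, 20), 100 * band_power(psd, 52, 100))
  flat <- structure(list(freqs = 0:250, power = rep(3.7, 251)),
                    class = "psd_estimate")
  expect_equal(band_power(flat, 10, 20), 3.7)
  expect_equal(band_power(flat, 0.5, 10), 3.7)
})

test_that("spectral entropy spans its analytic extremes", {
  single <- structure(list(freqs = 0:250, power = c(rep(0, 100), 1,
                                                    rep(0, 150))),
                      class = "psd_estimate")
  expect_equal(spectral_entropy(single), 0)
  flat <- structure(list(freqs = 0:250, power = rep(1, 251)),
                    class = "psd_estimate")
  expect_equal(spectral_entropy(flat), 1)
  set.seed(7)
  h <- replicate(20, spectral_entropy(estimate_psd(rnorm(5 * fs), fs)))
  expect_gt(mean(h), 0.9)
})

test_that("baseline standard deviation follows the moving-average filter", {
  expect_equal(baseline_std(rep(5, 5 * fs), fs), 0)
  # 0.2 Hz passes the 1-s average nearly unattenuated
  slow <- 3 * sin(2 * pi * 0.2 * t5)
  expect_lt(abs(baseline_std(slow, fs) - 3 / sqrt(2)) / (3 / sqrt(2)), 0.15)
  # 50 Hz is averaged out by the Dirichlet kernel of the 1-s window
  fast <- 3 * sin(2 * pi * 50 * t5)
  expect_lt(baseline_std(fast, fs), 0.02 * 3 / sqrt(2))
})

test_that("steepest slope matches ramps and sampled sines", {
  expect_equal(steepest_slope(cumsum(rep(2, 100)), fs), 1000)
  expect_equal(steepest_slope(rep(1, 100), fs), 0)
  f <- 7
  expect_equal(steepest_slope(sin(2 * pi * f * t5), fs), 2 * pi * f,
               tolerance = 0.05)
})

test_that("amplitude statistics are the signed extremes and population sd", {
  a <- amplitude_stats(c(-3, 0, 5))
  expect_equal(unname(a["HA"]), 5)
  expect_equal(unname(a["LA"]), -3)
  b <- amplitude_stats(rep(2.5, 10))
  expect_equal(unname(b["stdSQI"]), 0)
  s <- amplitude_stats(sin(2 * pi * 10 * t5))
  expect_equal(unname(s["stdSQI"]), 1 / sqrt(2), tolerance = 0.01)
})

test_that("moments use the non-excess population convention", {
  set.seed(10)
  ks <- replicate(100, {
    m <- moments(rnorm(2500)); unname(m["kSQI"])
  })
  expect_lt(abs(mean(ks) - 3), 0.3)
  two_point <- rep(c(1, -1), 100)
  m <- moments(two_point)
  expect_equal(unname(m["sSQI"]), 0)
  expect_equal(unname(m["kSQI"]), 1)
  degen <- moments(rep(4, 100))
  expect_true(attr(degen, "degenerate"))
  expect_identical(unname(degen[c("kSQI", "sSQI")]), c(0, 0))
  # ECG-like sparse spikes are leptokurtic
  w <- ecg_waveform(140, fs, 5, amp = 20, jitter = 0, qrs_width_s = 0.04)
  expect_gt(unname(moments(w$samples)["kSQI"]), 5)
})

test_that("power ratios respect band containment", {
  p10 <- power_ratios(estimate_psd(sin(2 * pi * 10 * t5), fs))
  expect_gte(unname(p10["pSQI"]), 0.99)
  p30 <- power_ratios(estimate_psd(sin(2 * pi * 30 * t5), fs))
  expect_lte(unname(p30["pSQI"]), 0.01)
  p15 <- power_ratios(estimate_psd(sin(2 * pi * 1.5 * t5), fs))
  expect_gte(unname(p15["basSQI"]), 0.99)
})

test_that("Hjorth complexity is 1 for a tone and above 1.2 for noise", {
  for (f in c(5, 25, 60)) {
    cx <- hjorth_complexity(sin(2 * pi * f * t5))
    expect_equal(as.numeric(cx), 1, tolerance = 0.02)
  }
  set.seed(11)
  cxn <- replicate(50, as.numeric(hjorth_complexity(rnorm(2500))))
  expect_gt(min(cxn), 1.2)
  mix <- sin(2 * pi * 5 * t5) + sin(2 * pi * 45 * t5)
  expect_gt(as.numeric(hjorth_complexity(mix)),
            max(as.numeric(hjorth_complexity(sin(2 * pi * 5 * t5))),
                as.numeric(hjorth_complexity(sin(2 * pi * 45 * t5)))))
})

test_that("the full vector is ordered canonically and flags degeneracy", {
  v <- compute_sqi_vector(numeric(5 * fs), fs)
  expect_true(attr(v, "degenerate"))
  expect_true(all(v == 0))
  expect_identical(names(v), sqi_feature_names())
  sim <- generate_recording(synth_config(
    n_abdominal_channels = 1, duration = 10, fetal_amp_per_channel = 30,
    maternal_gain_per_channel = 0.05, seed = 2))
  pre <- preprocess_recording(sim$recording, "train")
  seg <- segment_channel(pre$samples[1, ], pre$fs)[1, ]
  v <- compute_sqi_vector(seg, pre$fs)
  expect_gt(unname(v["kSQI"]), 3)
  expect_gt(unname(v["pband2"]), unname(v["pband5"]))
})

test_that("features scale covariantly with amplitude", {
  set.seed(12)
  x <- rnorm(5 * fs) + sin(2 * pi * 8 * t5)
  c_ <- 3.7
  v1 <- compute_sqi_vector(x, fs)
  v2 <- compute_sqi_vector(c_ * x, fs)
  linear <- c("HA", "LA", "stdSQI", "bas_pow", "ss")
  quadratic <- c("pband1", "pband2", "pband3", "pband4", "pband5")
  invariant <- c("seSQI", "kSQI", "sSQI", "pSQI", "basSQI", "complexity")
  expect_equal(v2[linear], c_ * v1[linear], tolerance = 1e-9)
  expect_equal(v2[quadratic], c_^2 * v1[quadratic], tolerance = 1e-9)
  expect_equal(v2[invariant], v1[invariant], tolerance = 1e-9)
})
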