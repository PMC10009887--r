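fs <- 500

# FIR mixture of references, optional fetal component added
make_mixture <- function(n = 10 * fs, seed = 1, fetal_amp = 0,
                         ref_noise = 0.5) {
  set.seed(seed)
  m <- ecg_waveform(80, fs, n / fs, amp = 100, jitter = 0.02, seed = seed,
                    qrs_width_s = 0.09)
  refs <- cbind(1.2 * m$samples + rnorm(n, sd = ref_noise),
                0.8 * m$samples + rnorm(n, sd = ref_noise),
                1.5 * m$samples + rnorm(n, sd = ref_noise))
  h <- list(c(0.9, rep(0, 9)), c(-0.3, 0.1, rep(0, 8)),
            c(0.2, rep(0, 8), 0.05))
  abdominal <- numeric(n)
  for (k in 1:3) {
    abdominal <- abdominal +
      as.numeric(stats::filter(refs[, k], h[[k]], sides = 1, method = "conv"))
  }
  abdominal[is.na(abdominal)] <- 0
  fet <- ecg_waveform(140, fs, n / fs, amp = fetal_amp, jitter = 0.02,
                      seed = seed + 1, qrs_width_s = 0.04)
  list(abdominal = abdominal + fet$samples, refs = refs,
       fetal = fet$samples, fetal_peaks = fet$peaks)
}

test_that("an FIR-explained abdominal trace is cancelled almost exactly", {
  set.seed(2)
  n <- 10 * fs
  ref1 <- as.numeric(stats::filter(rnorm(n), rep(1 / 3, 3), sides = 1))
  ref1[is.na(ref1)] <- 0
  h <- c(0.5, -0.2, 0.1, 0.05, 0, 0, 0.02, 0, 0, -0.01)
  d <- as.numeric(stats::filter(ref1, h, sides = 1, method = "conv"))
  d[is.na(d)] <- 0
  refs <- cbind(ref1, rnorm(n, sd = 0.01), rnorm(n, sd = 0.01))
  out <- qrd_rls_extract(d, refs, fs, extractor_config())
  # steady state: past several forgetting-factor memory lengths (~1000)
  ss <- (n - 2 * fs + 1):n
  expect_lt(mean(out$samples[ss]^2), 1e-6 * mean(d[ss]^2))
})

test_that("the fetal component survives maternal cancellation", {
  # the canceller's misadjustment absorbs a small share of the fetal
  # energy (a known property of RLS with short data memory); the output
  # must stay strongly correlated with the fetal source and agree with
  # the independent covariance-form estimator
  mix <- make_mixture(n = 10 * fs, seed = 3, fetal_amp = 20, ref_noise = 0.1)
  cfg <- extractor_config()
  out <- qrd_rls_extract(mix$abdominal, mix$refs, fs, cfg)
  ss <- 2001:length(mix$abdominal)
  got <- cor(out$samples[ss], mix$fetal[ss])
  expect_gt(got, 0.9)
  ora <- oracle_rls(mix$abdominal, mix$refs, taps = 20, lambda = 0.999,
                    delta = cfg$regularization)
  expect_equal(got, cor(ora$e[ss], mix$fetal[ss]), tolerance = 1e-6)
})

test_that("lambda = 1 weights solve the regularised normal equations", {
  set.seed(4)
  n <- 3 * fs
  refs <- cbind(rnorm(n), rnorm(n), rnorm(n))
  w_true <- rnorm(60)
  d <- numeric(n)
  for (k in 1:3) {
    d <- d + as.numeric(stats::filter(refs[, k],
                                      w_true[(k - 1) * 20 + 1:20],
                                      sides = 1, method = "conv"))
  }
  d[is.na(d)] <- 0
  d <- d + rnorm(n, sd = 0.1)
  cfg <- extractor_config(forgetting_factor = 1)
  out <- qrd_rls_extract(d, refs, fs, cfg)
  w_ls <- oracle_normal_eq(d, refs, taps = 20, delta = cfg$regularization)
  expect_lt(max(abs(out$weights - w_ls)) / max(abs(w_ls)), 1e-6)
})

test_that("QR-form output equals covariance-form RLS", {
  mix <- make_mixture(n = 4 * fs, seed = 5, fetal_amp = 10)
  cfg <- extractor_config()
  out <- qrd_rls_extract(mix$abdominal, mix$refs, fs, cfg)
  ora <- oracle_rls(mix$abdominal, mix$refs, taps = 20, lambda = 0.999,
                    delta = cfg$regularization)
  rel <- max(abs(out$samples - ora$e)) /
    max(abs(mix$abdominal))
  expect_lt(rel, 1e-6)
})

test_that("output is invariant to joint scaling of the maternal component", {
  # scaling the maternal pickup in both the abdominal trace and the
  # references leaves the fetal residual unchanged once the influence of
  # the (fixed, unscaled) regularised initialisation has been forgotten
  mix <- make_mixture(n = 20 * fs, seed = 6, fetal_amp = 20, ref_noise = 0.1)
  cfg <- extractor_config()
  maternal_part <- mix$abdominal - mix$fetal
  o1 <- qrd_rls_extract(mix$abdominal, mix$refs, fs, cfg)
  o2 <- qrd_rls_extract(5 * maternal_part + mix$fetal, 5 * mix$refs, fs, cfg)
  n <- length(mix$abdominal)
  ss <- (n - 2 * fs + 1):n
  expect_lt(max(abs(o2$samples[ss] - o1$samples[ss])) /
              max(abs(o1$samples[ss])), 1e-6)
})

test_that("length and configuration mismatches are rejected", {
  expect_error(qrd_rls_extract(rnorm(1000), cbind(rnorm(999)), fs,
                               extractor_config(n_references = 1)),
               "same length")
  expect_error(qrd_rls_extract(rnorm(1000), cbind(rnorm(1000)), fs,
                               extractor_config(n_references = 3)),
               "reference leads")
  expect_error(extractor_config(forgetting_factor = 0), "forgetting_factor")
})

test_that("maxsearch finds clean impulse trains of either polarity", {
  n <- 10 * fs
  w <- ecg_waveform(140, fs, 10, amp = 10, jitter = 0, qrs_width_s = 0.04)
  det <- maxsearch_detect(w$samples, detector_config(), fs = fs)
  expect_identical(det$indices, w$peaks)
  det_neg <- maxsearch_detect(-w$samples, detector_config(), fs = fs)
  expect_identical(det_neg$indices, w$peaks)
})

test_that("maxsearch is robust to moderate noise", {
  f1s <- vapply(1:20, function(s) {
    w <- ecg_waveform(140, fs, 30, amp = 10, jitter = 0.02, seed = s,
                      qrs_width_s = 0.04)
    set.seed(s)
    snr_lin <- 10^(10 / 10)
    noise <- rnorm(length(w$samples),
                   sd = sqrt(mean(w$samples^2) / snr_lin))
    det <- maxsearch_detect(w$samples + noise, detector_config(), fs = fs)
    ref <- peak_annotations(w$peaks, fs = fs)
    unname(detection_metrics(match_peaks(det, ref, 50))["F1det"])
  }, numeric(1))
  expect_gte(mean(f1s), 0.99)
})

test_that("detected inter-peak intervals track the simulated fetal rate", {
  for (r in c(110, 130, 160)) {
    w <- ecg_waveform(r, fs, 20, amp = 10, jitter = 0.02, seed = r,
                      qrs_width_s = 0.04)
    det <- maxsearch_detect(w$samples, detector_config(), fs = fs)
    med_rr <- median(diff(det$indices)) / fs
    expect_lt(abs(med_rr - 60 / r) / (60 / r), 0.05)
  }
})
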