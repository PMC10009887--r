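#' Names of the sixteen signal quality indexes
#'
#' Canonical order of the feature set: five band powers, spectral entropy,
#' baseline standard deviation, steepest slope, amplitude extremes and
#' standard deviation, kurtosis and skewness, the QRS-band power ratio, the
#' Hjorth complexity and the baseline power ratio.
#'
#' @return Character vector of length 16.
#' @export
sqi_feature_names <- function() {
  c("pband2", "seSQI", "pband4", "bas_pow", "pband3", "ss", "pband1",
    "HA", "stdSQI", "kSQI", "pband5", "LA", "pSQI", "complexity",
    "basSQI", "sSQI")
}

#' Welch power spectral density of a segment
#'
#' Welch's averaged modified periodogram: 1-s Hann windows, 50% overlap,
#' one-sided density normalisation. With 1-s windows the frequency grid
#' spacing equals 1 Hz, enough to resolve the narrow 48--52 Hz powerline
#' band. An all-zero segment yields a valid all-zero PSD.
#'
#' @param seg Numeric vector of at least `2 * fs` samples, microvolt.
#' @param fs Sampling rate in Hz.
#' @return An object of class `psd_estimate`: list with `freqs` (Hz,
#'   ascending 0..fs/2) and `power` (one-sided density, uV^2/Hz).
#' @export
estimate_psd <- function(seg, fs) {
  stopifnot(is.numeric(seg), fs > 0)
  if (length(seg) < 2 * fs) {
    stop("segment must be at least 2 s long", call. = FALSE)
  }
  L <- round(fs)                       # 1-s window
  step <- floor(L / 2)                 # 50% overlap
  w <- 0.5 * (1 - cos(2 * pi * (0:(L - 1)) / L))   # periodic Hann
  U <- sum(w^2)
  starts <- seq(1, length(seg) - L + 1, by = step)
  n_half <- floor(L / 2)
  acc <- numeric(n_half + 1)
  for (s in starts) {
    X <- fft(seg[s:(s + L - 1)] * w)
    pxx <- Mod(X[1:(n_half + 1)])^2 / (fs * U)
    if (L %% 2 == 0) {
      pxx[2:n_half] <- 2 * pxx[2:n_half]           # one-sided, keep DC/Nyquist
    } else {
      pxx[2:(n_half + 1)] <- 2 * pxx[2:(n_half + 1)]
    }
    acc <- acc + pxx
  }
  structure(list(freqs = (0:n_half) * fs / L,
                 power = acc / length(starts)),
            class = "psd_estimate")
}

#' Mean power density in a frequency band
#'
#' Mean of the PSD bins with `f_lo <= f <= f_hi` (both endpoints inclusive).
#'
#' @param psd A [estimate_psd()] result.
#' @param f_lo,f_hi Band edges in Hz, `0 <= f_lo < f_hi <= fs/2`.
#' @return Scalar mean density, uV^2/Hz.
#' @export
band_power <- function(psd, f_lo, f_hi) {
  stopifnot(inherits(psd, "psd_estimate"), f_lo >= 0, f_lo < f_hi)
  sel <- psd$freqs >= f_lo & psd$freqs <= f_hi
  if (!any(sel)) stop("no PSD bins inside the requested band", call. = FALSE)
  mean(psd$power[sel])
}

# Integrated (summed) band power; used for the two power ratios so unequal
# band widths are handled identically in numerator and denominator.
band_power_sum <- function(psd, f_lo, f_hi) {
  sel <- psd$freqs >= f_lo & psd$freqs <= f_hi
  if (!any(sel)) stop("no PSD bins inside the requested band", call. = FALSE)
  sum(psd$power[sel])
}

#' Normalised spectral entropy
#'
#' Shannon entropy of the PSD normalised to a probability distribution,
#' divided by `log(n_bins)` so the result lies in \[0, 1\]: 0 for a single
#' occupied bin, 1 for a flat spectrum. Zero-power bins contribute nothing;
#' an all-zero PSD is defined as 0.
#'
#' @param psd A [estimate_psd()] result.
#' @return Scalar in \[0, 1\].
#' @export
spectral_entropy <- function(psd) {
  stopifnot(inherits(psd, "psd_estimate"), length(psd$power) >= 2)
  tot <- sum(psd$power)
  if (tot == 0) return(0)
  p <- psd$power / tot
  p <- p[p > 0]
  -sum(p * log(p)) / log(length(psd$power))
}

#' Baseline standard deviation (bas_pow)
#'
#' The baseline is extracted with a single-stage centred moving average over
#' a 1-s window (length forced odd, edges reflected); the index is the
#' population standard deviation of that baseline trace.
#'
#' @param seg Numeric vector, microvolt.
#' @param fs Sampling rate in Hz.
#' @return Scalar, microvolt.
#' @export
baseline_std <- function(seg, fs) {
  w <- round(fs)
  if (w %% 2 == 0) w <- w + 1L
  half <- (w - 1L) / 2L
  n <- length(seg)
  padded <- c(rev(seg[2:(half + 1)]), seg, rev(seg[(n - half):(n - 1)]))
  cs <- cumsum(c(0, padded))
  baseline <- (cs[(w + 1):(w + n)] - cs[1:n]) / w
  pop_sd(baseline)
}

#' Steepest slope (ss)
#'
#' Maximum absolute first difference scaled to microvolt per second.
#'
#' @param seg Numeric vector of at least 2 samples, microvolt.
#' @param fs Sampling rate in Hz.
#' @return Scalar, uV/s.
#' @export
steepest_slope <- function(seg, fs) {
  stopifnot(length(seg) >= 2)
  max(abs(diff(seg))) * fs
}

#' Amplitude extremes and standard deviation (HA, LA, stdSQI)
#'
#' @param seg Numeric vector, microvolt.
#' @return Named vector: `HA` (signed maximum), `LA` (signed minimum),
#'   `stdSQI` (population standard deviation), all in microvolt.
#' @export
amplitude_stats <- function(seg) {
  stopifnot(length(seg) >= 1)
  c(HA = max(seg), LA = min(seg), stdSQI = pop_sd(seg))
}

#' Kurtosis and skewness (kSQI, sSQI)
#'
#' Population (biased) estimators; kurtosis is non-excess, so Gaussian noise
#' scores 3. A zero-variance segment is degenerate: both moments are
#' reported as 0 with the `degenerate` attribute set.
#'
#' @param seg Numeric vector, microvolt.
#' @return Named vector `c(kSQI, sSQI)` with attribute `degenerate`.
#' @export
moments <- function(seg) {
  m <- mean(seg)
  m2 <- mean((seg - m)^2)
  if (m2 == 0) {
    return(structure(c(kSQI = 0, sSQI = 0), degenerate = TRUE))
  }
  structure(c(kSQI = mean((seg - m)^4) / m2^2,
              sSQI = mean((seg - m)^3) / m2^1.5),
            degenerate = FALSE)
}

#' QRS-band and baseline power ratios (pSQI, basSQI)
#'
#' `pSQI` is the power in 5--15 Hz over the power in 5--45 Hz (the relative
#' power in the fetal QRS band); `basSQI` is the power in 0--3 Hz over the
#' power in 0--100 Hz (relative residual baseline power). Both use
#' integrated (summed) bin powers so the unequal band widths cancel
#' identically; the 100 Hz edge is truncated at the Nyquist frequency when
#' the sampling rate is below 200 Hz. A zero denominator yields 0 with the
#' `degenerate` attribute set.
#'
#' @param psd A [estimate_psd()] result.
#' @return Named vector `c(pSQI, basSQI)` with attribute `degenerate`.
#' @export
power_ratios <- function(psd) {
  stopifnot(inherits(psd, "psd_estimate"))
  nyq <- max(psd$freqs)
  num_p <- band_power_sum(psd, 5, 15)
  den_p <- band_power_sum(psd, 5, 45)
  num_b <- band_power_sum(psd, 0, 3)
  den_b <- band_power_sum(psd, 0, min(100, nyq))
  degen <- den_p == 0 || den_b == 0
  c_p <- if (den_p == 0) 0 else num_p / den_p
  c_b <- if (den_b == 0) 0 else num_b / den_b
  structure(c(pSQI = c_p, basSQI = c_b), degenerate = degen)
}

#' Hjorth complexity
#'
#' Mobility of a series is the square root of the variance of its first
#' difference over its own variance; complexity is the mobility of the first
#' difference over the mobility of the signal. Any real signal scores at
#' least 1; a pure sinusoid scores exactly 1. Zero variance at any stage is
#' degenerate (reported as 0 with the `degenerate` attribute).
#'
#' @param seg Numeric vector, microvolt.
#' @return Scalar with attribute `degenerate`.
#' @export
hjorth_complexity <- function(seg) {
  v0 <- pop_var(seg)
  d1 <- diff(seg)
  v1 <- pop_var(d1)
  v2 <- pop_var(diff(d1))
  if (v0 == 0 || v1 == 0) {
    return(structure(0, degenerate = TRUE))
  }
  structure(sqrt(v2 / v1) / sqrt(v1 / v0), degenerate = FALSE)
}

#' Compute the full sixteen-index quality vector of a 5-s segment
#'
#' @param seg Numeric vector (one preprocessed 5-s segment), microvolt.
#' @param fs Sampling rate in Hz.
#' @return Named numeric vector in the order of [sqi_feature_names()], with
#'   attribute `degenerate` (`TRUE` for zero-variance or otherwise
#'   pathological segments, whose moment/ratio features are recorded as 0).
#' @export
compute_sqi_vector <- function(seg, fs) {
  stopifnot(is.numeric(seg), length(seg) >= 2)
  if (pop_var(seg) == 0) {
    out <- stats::setNames(numeric(16), sqi_feature_names())
    return(structure(out, degenerate = TRUE))
  }
  psd <- estimate_psd(seg, fs)
  mom <- moments(seg)
  rat <- power_ratios(psd)
  cx <- hjorth_complexity(seg)
  amp <- amplitude_stats(seg)
  out <- c(
    pband2 = band_power(psd, 10, 20),
    seSQI = spectral_entropy(psd),
    pband4 = band_power(psd, 48, 52),
    bas_pow = baseline_std(seg, fs),
    pband3 = band_power(psd, 20, 48),
    ss = steepest_slope(seg, fs),
    pband1 = band_power(psd, 0.5, 10),
    HA = unname(amp["HA"]),
    stdSQI = unname(amp["stdSQI"]),
    kSQI = unname(mom["kSQI"]),
    pband5 = band_power(psd, 52, min(100, max(psd$freqs))),
    LA = unname(amp["LA"]),
    pSQI = unname(rat["pSQI"]),
    complexity = as.numeric(cx),
    basSQI = unname(rat["basSQI"]),
    sSQI = unname(mom["sSQI"])
  )
  structure(out,
            degenerate = attr(mom, "degenerate") || attr(rat, "degenerate") ||
              attr(cx, "degenerate"))
}

# Population (biased) variance / standard deviation.
pop_var <- function(x) mean((x - mean(x))^2)
pop_sd <- function(x) sqrt(pop_var(x))
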