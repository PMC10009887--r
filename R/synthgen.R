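#' Synthetic abdominal recording configuration
#'
#' Bundles every knob of the synthetic multi-channel abdominal ECG generator.
#' Defaults emulate a mid-gestation acquisition: 24 single-ended abdominal
#' channels plus 3 fetal-free thoracic reference leads at 500 Hz, a dominant
#' maternal ECG, a per-channel fetal ECG whose amplitude (possibly zero) makes
#' some channels informative and some not, sub-1-Hz baseline wander, 50 Hz
#' powerline interference and broadband noise.
#'
#' @param n_abdominal_channels Number of abdominal channels.
#' @param n_reference_channels Number of thoracic (maternal-only) reference
#'   leads.
#' @param fs Sampling frequency in Hz.
#' @param duration Recording length in seconds; `duration * fs` must be an
#'   integer and at least 5 s worth of samples.
#' @param maternal_rate,fetal_rate Heart rates in beats/min. Typical ranges
#'   are 60--100 (maternal) and 110--160 (fetal).
#' @param maternal_amp Maternal R-wave amplitude in microvolt before
#'   per-channel gain.
#' @param fetal_amp_per_channel Numeric vector, one fetal R-wave amplitude in
#'   microvolt per abdominal channel (0 allowed: no fetal content).
#' @param maternal_gain_per_channel Optional per-abdominal-channel gain for the
#'   maternal component (0 allowed). `NULL` draws gains from the seed.
#' @param hr_jitter Fractional standard deviation of the RR intervals
#'   (multiplicative Gaussian, truncated at three sigma).
#' @param baseline_amp,baseline_freq Baseline wander amplitude (microvolt) and
#'   frequency (Hz, below 1 Hz).
#' @param powerline_amp Amplitude of the 50 Hz powerline component, microvolt.
#' @param noise_std Standard deviation of the additive white noise, microvolt.
#' @param seed Integer seed; identical configuration and seed give
#'   bit-identical output.
#' @return An object of class `synth_config`.
#' @seealso [generate_recording()]
#' @export
synth_config <- function(n_abdominal_channels = 24L,
                         n_reference_channels = 3L,
                         fs = 500,
                         duration = 60,
                         maternal_rate = 80,
                         fetal_rate = 140,
                         maternal_amp = 100,
                         fetal_amp_per_channel = rep(10, n_abdominal_channels),
                         maternal_gain_per_channel = NULL,
                         hr_jitter = 0.02,
                         baseline_amp = 30,
                         baseline_freq = 0.25,
                         powerline_amp = 2,
                         noise_std = 3,
                         seed = 1L) {
  stopifnot(n_abdominal_channels >= 1, n_reference_channels >= 0,
            fs > 0, maternal_rate > 0, fetal_rate > 0,
            maternal_amp >= 0, all(fetal_amp_per_channel >= 0),
            hr_jitter >= 0, baseline_amp >= 0, baseline_freq < 1,
            powerline_amp >= 0, noise_std >= 0)
  if (duration <= 0) {
    stop("`duration` must be positive", call. = FALSE)
  }
  n <- duration * fs
  if (abs(n - round(n)) > 1e-9 || round(n) < 5 * fs) {
    stop("`duration * fs` must be an integer of at least 5 s worth of samples",
         call. = FALSE)
  }
  if (length(fetal_amp_per_channel) != n_abdominal_channels) {
    stop("`fetal_amp_per_channel` must have one entry per abdominal channel",
         call. = FALSE)
  }
  if (!is.null(maternal_gain_per_channel) &&
      length(maternal_gain_per_channel) != n_abdominal_channels) {
    stop("`maternal_gain_per_channel` must have one entry per abdominal channel",
         call. = FALSE)
  }
  structure(list(
    n_abdominal_channels = as.integer(n_abdominal_channels),
    n_reference_channels = as.integer(n_reference_channels),
    fs = fs, duration = duration,
    maternal_rate = maternal_rate, fetal_rate = fetal_rate,
    maternal_amp = maternal_amp,
    fetal_amp_per_channel = as.numeric(fetal_amp_per_channel),
    maternal_gain_per_channel = maternal_gain_per_channel,
    hr_jitter = hr_jitter,
    baseline_amp = baseline_amp, baseline_freq = baseline_freq,
    powerline_amp = powerline_amp, noise_std = noise_std,
    seed = as.integer(seed)
  ), class = "synth_config")
}

#' Quasi-periodic ECG-like waveform
#'
#' Generates a train of beat templates, each a sum of Gaussian bumps
#' approximating the P-QRS-T morphology, with RR intervals drawn around
#' `60/rate` seconds. The QRS width defaults to values typical of a fetal
#' (about 40 ms) or maternal (about 90 ms) complex.
#'
#' @param rate Heart rate in beats/min.
#' @param fs Sampling frequency in Hz (at least 100).
#' @param duration Duration in seconds (positive).
#' @param amp R-wave amplitude in microvolt; 0 yields an all-zero trace but
#'   peak indices are still returned at the template centres.
#' @param jitter Fractional standard deviation of the RR intervals; 0 gives a
#'   strictly periodic train with RR `round(fs * 60 / rate)` samples.
#' @param seed Integer seed for the RR jitter.
#' @param qrs_width_s Total QRS width in seconds.
#' @return A list with `samples` (microvolt) and `peaks` (0-based sample
#'   indices of the R-wave maxima, strictly increasing).
#' @export
ecg_waveform <- function(rate, fs, duration, amp = 1, jitter = 0,
                         seed = 1L, qrs_width_s = 0.09) {
  stopifnot(rate > 0, fs >= 100)
  if (duration <= 0) stop("`duration` must be positive", call. = FALSE)
  n <- round(duration * fs)
  rr_nom <- 60 / rate
  rr_nom_samp <- round(fs * rr_nom)

  # RR jitter: i.i.d. multiplicative Gaussian truncated at +/- 3 sigma
  n_beats_max <- ceiling(duration / rr_nom) + 3L
  if (jitter > 0) {
    set.seed(seed)
    z <- rnorm(n_beats_max)
    z <- pmax(pmin(z, 3), -3)
    rr <- round(rr_nom_samp * (1 + jitter * z))
    rr <- pmax(rr, ceiling(0.5 * rr_nom_samp))
  } else {
    rr <- rep(rr_nom_samp, n_beats_max)
  }
  first <- round(rr_nom_samp / 2)
  peaks <- cumsum(c(first, rr))
  peaks <- peaks[peaks < n]            # 0-based centres inside the trace

  x <- numeric(n)
  if (length(peaks) > 0) {
    # Beat template: Q, R, S narrow Gaussians plus broad P and T bumps.
    sig_r <- qrs_width_s / 5
    qs_off <- qrs_width_s / 2.2
    p_off <- -0.30 * rr_nom; t_off <- 0.35 * rr_nom
    sig_p <- 0.06 * rr_nom;  sig_t <- 0.10 * rr_nom
    half <- ceiling(0.45 * rr_nom * fs)
    rel <- (-half):half
    t_rel <- rel / fs
    template <- amp * (
      exp(-t_rel^2 / (2 * sig_r^2)) -
        0.20 * exp(-(t_rel + qs_off)^2 / (2 * (sig_r / 1.5)^2)) -
        0.30 * exp(-(t_rel - qs_off)^2 / (2 * (sig_r / 1.5)^2)) +
        0.12 * exp(-(t_rel - p_off)^2 / (2 * sig_p^2)) +
        0.25 * exp(-(t_rel - t_off)^2 / (2 * sig_t^2)))
    for (p in peaks) {
      idx <- p + rel                  # 0-based
      keep <- idx >= 0 & idx < n
      x[idx[keep] + 1L] <- x[idx[keep] + 1L] + template[keep]
    }
  }
  list(samples = x, peaks = as.integer(peaks))
}

#' Per-channel gain profile of the simulated electrode array
#'
#' Models electrode proximity to the two cardiac sources: a fraction of the
#' abdominal electrodes sit close to the fetus (strong fetal pickup, weak
#' maternal pickup) and the rest are maternal-dominated. Used to draw the
#' per-channel fetal amplitudes and maternal gains of a study recording so
#' that roughly a quarter of the channels carry fetal content above the 5 dB
#' labelling threshold.
#'
#' @param n_channels Number of abdominal channels.
#' @param informative_frac Expected fraction of fetal-proximal channels.
#' @param seed Integer seed.
#' @return A list with numeric vectors `fetal_amp` (microvolt) and
#'   `maternal_gain` (dimensionless).
#' @export
study_channel_profile <- function(n_channels = 24L, informative_frac = 0.25,
                                  seed = 1L) {
  set.seed(seed)
  proximal <- runif(n_channels) < informative_frac
  fetal_amp <- ifelse(proximal, runif(n_channels, 30, 50),
                      runif(n_channels, 0, 5))
  maternal_gain <- ifelse(proximal, runif(n_channels, 0.02, 0.10),
                          runif(n_channels, 0.45, 1.2))
  list(fetal_amp = as.numeric(fetal_amp),
       maternal_gain = as.numeric(maternal_gain))
}

#' Configuration of one simulated study recording
#'
#' Convenience wrapper building a [synth_config()] whose per-channel fetal
#' amplitudes and maternal gains follow [study_channel_profile()], with the
#' fetal and maternal rates drawn uniformly from the normal mid-gestation
#' ranges (110--160 and 60--100 beats/min).
#'
#' @param seed Integer seed (also drives the gain profile).
#' @param duration Recording length in seconds.
#' @param n_channels Number of abdominal channels.
#' @param informative_frac Expected fraction of fetal-proximal channels.
#' @return A `synth_config`.
#' @export
study_recording_config <- function(seed, duration = 30, n_channels = 24L,
                                   informative_frac = 0.25) {
  prof <- study_channel_profile(n_channels, informative_frac, seed = seed)
  set.seed(seed + 1L)
  synth_config(
    n_abdominal_channels = n_channels,
    duration = duration,
    maternal_rate = runif(1, 60, 100),
    fetal_rate = runif(1, 110, 160),
    fetal_amp_per_channel = prof$fetal_amp,
    maternal_gain_per_channel = prof$maternal_gain,
    noise_std = 2,
    seed = seed
  )
}

#' Generate a synthetic multi-channel abdominal recording
#'
#' Each abdominal channel is the sum of the maternal ECG scaled by a
#' per-channel gain, the fetal ECG scaled by its per-channel amplitude,
#' sinusoidal baseline wander and 50 Hz powerline interference (random phase
#' per channel) and white Gaussian noise. Reference channels contain only the
#' maternal component (distinct gains) plus a small amount of noise. The
#' ground truth carries both R-peak trains and the per-channel true fetal
#' signal-to-noise ratio, defined as the power of the fetal component over
#' the power of everything else in that channel after the same 1 Hz
#' fourth-order Butterworth high-pass used by the feature pipeline, so that
#' labels derived from it match what the classifier sees.
#'
#' @param config A [synth_config()].
#' @return A list with `recording` (an [mc_recording()]) and `truth`, itself a
#'   list with `fetal_peaks`, `maternal_peaks` (0-based indices) and
#'   `true_fetal_snr` in dB per abdominal channel (`-Inf` where the fetal
#'   amplitude is zero, `+Inf` for a noise-free fetal-only channel).
#' @export
generate_recording <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  fs <- config$fs
  n <- round(config$duration * fs)
  n_ab <- config$n_abdominal_channels
  n_ref <- config$n_reference_channels

  mat <- ecg_waveform(config$maternal_rate, fs, config$duration, amp = 1,
                      jitter = config$hr_jitter, seed = config$seed,
                      qrs_width_s = 0.09)
  fet <- ecg_waveform(config$fetal_rate, fs, config$duration, amp = 1,
                      jitter = config$hr_jitter, seed = config$seed + 1L,
                      qrs_width_s = 0.04)

  set.seed(config$seed + 2L)
  g_m <- config$maternal_gain_per_channel
  if (is.null(g_m)) g_m <- runif(n_ab, 0.4, 1.2)
  g_ref <- runif(max(n_ref, 1L), 0.8, 1.5)[seq_len(n_ref)]
  ph_base <- runif(n_ab, 0, 2 * pi)
  ph_line <- runif(n_ab, 0, 2 * pi)

  t <- (0:(n - 1)) / fs
  m_uv <- config$maternal_amp * mat$samples
  signals <- matrix(0, nrow = n_ab + n_ref, ncol = n)
  fetal_part <- matrix(0, nrow = n_ab, ncol = n)
  for (i in seq_len(n_ab)) {
    fetal_part[i, ] <- config$fetal_amp_per_channel[i] * fet$samples
    clean <- g_m[i] * m_uv + fetal_part[i, ] +
      config$baseline_amp * sin(2 * pi * config$baseline_freq * t + ph_base[i]) +
      config$powerline_amp * sin(2 * pi * 50 * t + ph_line[i])
    signals[i, ] <- clean + rnorm(n, sd = config$noise_std)
  }
  for (j in seq_len(n_ref)) {
    signals[n_ab + j, ] <- g_ref[j] * m_uv +
      rnorm(n, sd = 0.5 * config$noise_std)
  }

  roles <- c(rep("abdominal", n_ab), rep("reference", n_ref))
  nms <- c(sprintf("ABD%02d", seq_len(n_ab)),
           if (n_ref > 0) sprintf("REF%d", seq_len(n_ref)))
  rec <- mc_recording(signals, fs = fs, channel_roles = roles,
                      channel_names = nms,
                      meta = list(generator = "fecgsqa-synth",
                                  seed = config$seed))

  hp <- filter_spec(cutoff = 1, order = 4)
  snr <- vapply(seq_len(n_ab), function(i) {
    if (config$fetal_amp_per_channel[i] == 0) return(-Inf)
    f_hp <- highpass(fetal_part[i, ], hp, fs = fs)
    o_hp <- highpass(signals[i, ] - fetal_part[i, ], hp, fs = fs)
    p_f <- mean(f_hp^2)
    p_o <- mean(o_hp^2)
    if (p_o == 0) return(Inf)
    10 * log10(p_f / p_o)
  }, numeric(1))

  list(recording = rec,
       truth = list(fetal_peaks = fet$peaks,
                    maternal_peaks = mat$peaks,
                    true_fetal_snr = snr))
}
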