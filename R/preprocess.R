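#' High-pass filter specification
#'
#' Butterworth high-pass presets used by the pipeline: 1 Hz, 4th order for
#' the training/feature pathway; 3 Hz, 5th order as the more aggressive
#' variant for recordings with strong baseline wander.
#'
#' @param cutoff -3 dB cut-off frequency in Hz.
#' @param order Filter order.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(cutoff = 1, order = 4) {
  stopifnot(cutoff > 0, order >= 1)
  structure(list(cutoff = cutoff, order = as.integer(order),
                 kind = "highpass-butterworth"),
            class = "filter_spec")
}

#' Apply a causal Butterworth high-pass
#'
#' Single-pass (causal) IIR filtering, honouring the real-time monitoring
#' use case; no zero-phase refiltering. Operates on a plain numeric vector,
#' a channels-by-samples matrix, or an [mc_recording()] (per channel).
#'
#' @param x Numeric vector, matrix, or `mc_recording`.
#' @param spec A [filter_spec()].
#' @param fs Sampling rate in Hz (taken from the recording when `x` is one).
#' @return Same type as `x`, filtered.
#' @export
highpass <- function(x, spec = filter_spec(), fs = NULL) {
  stopifnot(inherits(spec, "filter_spec"))
  if (inherits(x, "mc_recording")) {
    x$samples <- highpass(x$samples, spec, fs = x$fs)
    return(x)
  }
  if (is.null(fs)) stop("`fs` is required", call. = FALSE)
  if (spec$cutoff >= fs / 2) {
    stop("cut-off must be below the Nyquist frequency", call. = FALSE)
  }
  bf <- signal::butter(spec$order, spec$cutoff / (fs / 2), type = "high")
  if (is.matrix(x)) {
    t(apply(x, 1, function(ch) as.numeric(signal::filter(bf, ch))))
  } else {
    as.numeric(signal::filter(bf, x))
  }
}

#' Resample a recording
#'
#' Polyphase anti-aliased resampling of every channel to a new rate. The
#' rational resampling factor is the reduced fraction `target_fs / fs`
#' (rates are treated as exact); duration is preserved to within one sample.
#'
#' @param rec An [mc_recording()].
#' @param target_fs Target sampling rate in Hz.
#' @return The resampled `mc_recording` (identical object when
#'   `target_fs == fs`).
#' @export
resample_recording <- function(rec, target_fs) {
  stopifnot(inherits(rec, "mc_recording"))
  if (!is.numeric(target_fs) || length(target_fs) != 1 || target_fs <= 0) {
    stop("`target_fs` must be a positive scalar", call. = FALSE)
  }
  if (target_fs == rec$fs) return(rec)
  pq <- rational_factor(target_fs / rec$fs)
  n_out <- ceiling(ncol(rec$samples) * pq[1] / pq[2])
  out <- matrix(0, nrow = nrow(rec$samples), ncol = n_out)
  for (i in seq_len(nrow(out))) {
    y <- signal::resample(rec$samples[i, ], pq[1], pq[2])
    out[i, ] <- y[seq_len(n_out)]
  }
  rec$samples <- out
  rec$fs <- target_fs
  rec
}

# Reduced-fraction approximation of a positive ratio (continued fractions),
# exact for ratios of integer sampling rates.
rational_factor <- function(r, tol = 1e-9, max_den = 1e6) {
  stopifnot(r > 0)
  a0 <- floor(r)
  p0 <- 1; q0 <- 0; p1 <- a0; q1 <- 1
  x <- r - a0
  while (abs(p1 / q1 - r) > tol * r && q1 < max_den && x > 1e-15) {
    x <- 1 / x
    a <- floor(x)
    x <- x - a
    p2 <- a * p1 + p0; q2 <- a * q1 + q0
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
  }
  c(as.integer(p1), as.integer(q1))
}

#' Split a channel into consecutive 5-s segments
#'
#' Non-overlapping windows of exactly `round(5 * fs)` samples starting at
#' sample 0; any trailing remainder shorter than 5 s is discarded. A channel
#' shorter than 5 s yields zero segments.
#'
#' @param channel Numeric vector of samples.
#' @param fs Sampling rate in Hz.
#' @return A matrix with one row per segment (`round(5*fs)` columns); row
#'   names give the 0-based start sample of each segment.
#' @export
segment_channel <- function(channel, fs) {
  stopifnot(is.numeric(channel), fs > 0)
  len <- round(5 * fs)
  n_seg <- floor(length(channel) / len)
  if (n_seg == 0) {
    m <- matrix(numeric(0), nrow = 0, ncol = len)
    return(m)
  }
  starts <- (seq_len(n_seg) - 1L) * len      # 0-based
  m <- matrix(channel[seq_len(n_seg * len)], nrow = n_seg, ncol = len,
              byrow = TRUE)
  rownames(m) <- as.character(starts)
  m
}

#' Preprocessing presets
#'
#' `"train"` mirrors the feature/training pathway (resample to 500 Hz,
#' 1 Hz 4th-order Butterworth high-pass); `"ninfea"` mirrors the detection
#' evaluation variant (512 Hz, 3 Hz 5th-order high-pass for stronger
#' baseline wander). No notch filtering in either preset: the classifier is
#' expected to cope with powerline interference without narrowing the fetal
#' ECG band.
#'
#' @param preset `"train"` or `"ninfea"`.
#' @return A list with `target_fs` and a [filter_spec()].
#' @export
preprocess_preset <- function(preset = c("train", "ninfea")) {
  preset <- match.arg(preset)
  switch(preset,
         train = list(target_fs = 500, spec = filter_spec(1, 4)),
         ninfea = list(target_fs = 512, spec = filter_spec(3, 5)))
}

#' Resample and high-pass a recording with a named preset
#'
#' The whole channel is filtered before segmentation, so segment boundaries
#' never cut across filter transients.
#'
#' @param rec An [mc_recording()].
#' @param preset See [preprocess_preset()].
#' @return The preprocessed `mc_recording`.
#' @export
preprocess_recording <- function(rec, preset = "train") {
  p <- preprocess_preset(preset)
  rec <- resample_recording(rec, p$target_fs)
  highpass(rec, p$spec)
}
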