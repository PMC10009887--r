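#' Fetal QRS detector configuration
#'
#' A sliding-window local-maximum search driven by an expected heart rate:
#' a candidate R-peak must be the maximum of the polarity-corrected signal
#' within +/- `w` samples, `w = round(window_factor * fs / expected_rate)`.
#' The default expected rate of 2.2 Hz sits mid-way in the normal fetal
#' range (~132 beats/min).
#'
#' @param expected_rate Expected heart rate in Hz.
#' @param window_factor Fraction of the expected beat period used as the
#'   search half-window.
#' @param polarity `"auto"` (choose the sign whose extrema have the larger
#'   median magnitude), `"positive"` or `"negative"`.
#' @return An object of class `detector_config`.
#' @export
detector_config <- function(expected_rate = 2.2, window_factor = 0.5,
                            polarity = c("auto", "positive", "negative")) {
  stopifnot(expected_rate > 0, window_factor > 0)
  polarity <- match.arg(polarity)
  structure(list(expected_rate = expected_rate,
                 window_factor = window_factor,
                 polarity = polarity),
            class = "detector_config")
}

#' Maximum-search fetal R-peak detection
#'
#' Resolves the QRS polarity, collects the local maxima of the
#' polarity-corrected signal, and keeps them greedily in descending
#' amplitude order while enforcing a minimum inter-peak distance of one
#' search half-window (on a conflict the larger peak wins). Equivalent to
#' retaining exactly the samples that are the maximum within +/- `w`.
#'
#' @param fecg A `fecg_estimate` (from [qrd_rls_extract()]) or a numeric
#'   vector (then `fs` is required).
#' @param cfg A [detector_config()].
#' @param fs Sampling rate, only when `fecg` is a plain vector.
#' @return A [peak_annotations()] object (label `"fetal"`), possibly empty.
#' @export
maxsearch_detect <- function(fecg, cfg = detector_config(), fs = NULL) {
  if (inherits(fecg, "fecg_estimate")) {
    x <- fecg$samples
    fs <- fecg$fs
  } else {
    x <- as.numeric(fecg)
    if (is.null(fs)) stop("`fs` is required for a plain vector", call. = FALSE)
  }
  stopifnot(inherits(cfg, "detector_config"))
  if (length(x) < 2 * fs) stop("signal must be at least 2 s long",
                               call. = FALSE)
  w <- max(1L, round(cfg$window_factor * fs / cfg$expected_rate))

  sign_ <- switch(cfg$polarity,
                  positive = 1,
                  negative = -1,
                  auto = {
                    n_exp <- max(3L, floor(length(x) / fs * cfg$expected_rate))
                    top_pos <- median(sort(x, decreasing = TRUE)[seq_len(n_exp)])
                    top_neg <- median(sort(-x, decreasing = TRUE)[seq_len(n_exp)])
                    if (top_neg > top_pos) -1 else 1
                  })
  s <- sign_ * x

  n <- length(s)
  cand <- which(s[2:(n - 1)] > s[1:(n - 2)] & s[2:(n - 1)] >= s[3:n]) + 1L
  if (length(cand) == 0) {
    return(peak_annotations(integer(0), fs = fs, label = "fetal"))
  }
  cand <- cand[order(-s[cand], cand)]
  accepted <- integer(0)
  for (c_ in cand) {
    if (length(accepted) == 0 || all(abs(accepted - c_) > w)) {
      accepted <- c(accepted, c_)
    }
  }
  peak_annotations(sort(accepted) - 1L, fs = fs, label = "fetal")
}
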