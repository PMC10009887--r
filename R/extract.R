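#' Adaptive maternal-ECG canceller configuration
#'
#' Defaults follow common practice for multi-reference recursive
#' least-squares fetal ECG extraction: 20 taps per thoracic reference, a
#' forgetting factor of 0.999 (an effective memory of about 1000 samples)
#' and three non-coplanar maternal reference leads.
#'
#' @param taps_per_reference Delay-line length per reference.
#' @param forgetting_factor Exponential weighting factor in (0, 1].
#' @param n_references Number of thoracic reference leads.
#' @param regularization Initial value of the triangular square-root factor
#'   (small positive; keeps the start-up well conditioned).
#' @return An object of class `extractor_config`.
#' @export
extractor_config <- function(taps_per_reference = 20L,
                             forgetting_factor = 0.999,
                             n_references = 3L,
                             regularization = 0.01) {
  stopifnot(taps_per_reference >= 1,
            forgetting_factor > 0, forgetting_factor <= 1,
            n_references >= 1, regularization > 0)
  structure(list(taps_per_reference = as.integer(taps_per_reference),
                 forgetting_factor = forgetting_factor,
                 n_references = as.integer(n_references),
                 regularization = regularization),
            class = "extractor_config")
}

#' Multi-reference QRD-RLS fetal ECG extraction
#'
#' Cancels the maternal ECG from one abdominal trace using the thoracic
#' reference leads: at each sample the regressor concatenates the last
#' `taps_per_reference` samples of every reference, the filter weights are
#' updated by exponentially weighted recursive least squares realised
#' through QR-decomposition (Givens rotation) updates, and the output is
#' the a priori estimation error -- the part of the abdominal signal the
#' references cannot explain, i.e. the fetal ECG plus residual noise.
#'
#' @param abdominal Numeric vector, one abdominal channel in microvolt.
#' @param references Numeric matrix (samples in rows, one column per
#'   reference lead) or a list of vectors, all the same length as
#'   `abdominal`.
#' @param fs Sampling rate in Hz.
#' @param cfg An [extractor_config()]; `n_references` must match.
#' @return An object of class `fecg_estimate`: list with `samples`
#'   (microvolt), `fs`, `weights` (final filter weights, references-major)
#'   and `transient` (number of start-up samples, `10 * taps`, to exclude
#'   from scoring).
#' @export
qrd_rls_extract <- function(abdominal, references, fs,
                            cfg = extractor_config()) {
  stopifnot(inherits(cfg, "extractor_config"))
  if (is.list(references) && !is.data.frame(references)) {
    references <- do.call(cbind, references)
  }
  references <- as.matrix(references)
  if (nrow(references) != length(abdominal)) {
    stop("abdominal and reference signals must have the same length",
         call. = FALSE)
  }
  if (ncol(references) != cfg$n_references) {
    stop("number of reference leads does not match the configuration",
         call. = FALSE)
  }
  if (length(abdominal) < 10 * cfg$taps_per_reference) {
    stop("signal shorter than ten delay lines", call. = FALSE)
  }
  out <- .qrd_rls_core(as.numeric(abdominal), references,
                       cfg$taps_per_reference, cfg$forgetting_factor,
                       cfg$regularization)
  structure(list(samples = out$e, fs = fs, weights = out$weights,
                 transient = 10L * cfg$taps_per_reference),
            class = "fecg_estimate")
}

#' Extract fetal ECG estimates for a set of abdominal channels
#'
#' Applies [qrd_rls_extract()] to each requested abdominal channel of a
#' recording, using all its reference channels as the noise references.
#'
#' @param rec An [mc_recording()] containing reference channels.
#' @param channels Abdominal channel indices to process (default: all).
#' @param cfg An [extractor_config()]; its `n_references` is set to the
#'   number of reference channels found.
#' @return Named list of `fecg_estimate` objects.
#' @export
extract_fecg <- function(rec, channels = NULL, cfg = extractor_config()) {
  stopifnot(inherits(rec, "mc_recording"))
  refs <- which(rec$channel_roles == "reference")
  if (length(refs) == 0) stop("recording has no reference channels",
                              call. = FALSE)
  cfg$n_references <- length(refs)
  abd <- which(rec$channel_roles == "abdominal")
  channels <- channels %||% abd
  stopifnot(all(channels %in% abd))
  ref_mat <- t(rec$samples[refs, , drop = FALSE])
  out <- lapply(channels, function(ch) {
    qrd_rls_extract(rec$samples[ch, ], ref_mat, rec$fs, cfg)
  })
  names(out) <- rec$channel_names[channels]
  out
}
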