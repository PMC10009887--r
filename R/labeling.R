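#' Template-based SNR of an extracted fetal ECG
#'
#' Aligns 100-ms windows centred on the annotated R-peaks, averages them into
#' a beat template, and contrasts the template power with the mean residual
#' power of the individual beats around it:
#' `SNR = 10 log10(mean(T^2) / mean over beats of mean((beat - T)^2))`.
#' Fewer than 3 usable peaks yields `-Inf`; identical noise-free beats yield
#' `+Inf`.
#'
#' @param fecg Numeric vector, extracted fetal ECG in microvolt.
#' @param fs Sampling rate in Hz.
#' @param peaks A [peak_annotations()] object (0-based indices at `fs`).
#' @return SNR in dB.
#' @export
estimate_fecg_snr <- function(fecg, fs, peaks) {
  stopifnot(is.numeric(fecg), fs > 0, inherits(peaks, "peak_annotations"))
  half <- round(0.05 * fs)
  idx <- peaks$indices
  idx <- idx[idx - half >= 0 & idx + half < length(fecg)]
  if (length(idx) < 3) return(-Inf)
  beats <- t(vapply(idx, function(p) fecg[(p - half):(p + half) + 1L],
                    numeric(2 * half + 1)))
  tmpl <- colMeans(beats)
  p_sig <- mean(tmpl^2)
  p_noise <- mean((beats - matrix(tmpl, nrow(beats), ncol(beats),
                                  byrow = TRUE))^2)
  if (p_noise == 0) return(Inf)
  10 * log10(p_sig / p_noise)
}

#' Binary informative labels from SNR values
#'
#' A channel (or segment) is informative only when its SNR is strictly above
#' the threshold; 5 dB exactly, or any non-finite low value, is
#' non-informative.
#'
#' @param snr Numeric vector of SNR values in dB (`-Inf` allowed).
#' @param threshold Decision threshold in dB.
#' @return Factor with levels `non_informative`, `informative`.
#' @export
assign_labels <- function(snr, threshold = 5) {
  stopifnot(is.finite(threshold))
  factor(ifelse(snr > threshold, "informative", "non_informative"),
         levels = c("non_informative", "informative"))
}

#' Balance a labelled feature table by random downsampling
#'
#' The majority class is downsampled without replacement to the minority
#' class size; row selection is deterministic given the seed.
#'
#' @param table Data frame with a `label` factor column.
#' @param seed Integer seed.
#' @return The balanced table (row order: original order of kept rows).
#' @export
balance_dataset <- function(table, seed = 1L) {
  stopifnot(is.data.frame(table), "label" %in% names(table))
  counts <- table(table$label)
  if (any(counts == 0)) {
    stop("both classes must be present to balance", call. = FALSE)
  }
  n_min <- min(counts)
  set.seed(seed)
  keep <- unlist(lapply(names(counts), function(cl) {
    rows <- which(table$label == cl)
    if (length(rows) > n_min) sort(sample(rows, n_min)) else rows
  }))
  table[sort(keep), , drop = FALSE]
}
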