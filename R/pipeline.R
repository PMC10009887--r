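#' Per-segment quality feature table of a recording
#'
#' Preprocesses a raw recording with the named preset, splits every
#' abdominal channel into consecutive 5-s segments, and computes the
#' sixteen quality indexes for each segment.
#'
#' @param rec An [mc_recording()].
#' @param preset Preprocessing preset, see [preprocess_preset()]; `NULL`
#'   skips preprocessing (the recording is used as-is).
#' @param recording_id Identifier stored in the provenance column.
#' @return Data frame with one row per (channel, segment): provenance
#'   columns `recording`, `channel` (index into the recording), `start`
#'   (0-based sample at the preprocessed rate), a logical `degenerate`
#'   flag, and the sixteen [sqi_feature_names()] columns.
#' @export
sqi_feature_table <- function(rec, preset = "train", recording_id = "rec") {
  stopifnot(inherits(rec, "mc_recording"))
  if (!is.null(preset)) rec <- preprocess_recording(rec, preset)
  abd <- which(rec$channel_roles == "abdominal")
  rows <- list()
  for (ch in abd) {
    segs <- segment_channel(rec$samples[ch, ], rec$fs)
    if (nrow(segs) == 0) next
    starts <- as.integer(rownames(segs))
    for (i in seq_len(nrow(segs))) {
      v <- compute_sqi_vector(segs[i, ], rec$fs)
      rows[[length(rows) + 1L]] <- data.frame(
        recording = recording_id, channel = ch, start = starts[i],
        degenerate = isTRUE(attr(v, "degenerate")),
        as.list(v), check.names = FALSE)
    }
  }
  if (length(rows) == 0) {
    stop("recording yields no 5-s segments", call. = FALSE)
  }
  do.call(rbind, rows)
}

#' Label a synthetic feature table from the generator's ground truth
#'
#' Assigns every segment of an abdominal channel the label derived from
#' that channel's true fetal SNR (strictly above the threshold =
#' informative). Using the ground-truth SNR removes any dependence on a
#' particular extraction algorithm when training on simulated data.
#'
#' @param table A [sqi_feature_table()] result.
#' @param truth The `truth` element of [generate_recording()].
#' @param threshold SNR threshold in dB.
#' @return The table with `label` and `true_snr` columns added.
#' @export
label_from_truth <- function(table, truth, threshold = 5) {
  snr <- truth$true_fetal_snr[table$channel]
  table$true_snr <- snr
  table$label <- assign_labels(snr, threshold)
  table
}

#' Build a balanced synthetic training set
#'
#' Simulates `n_recordings` study recordings (per-channel gains drawn from
#' the electrode-proximity profile of [study_recording_config()]), computes
#' the per-segment quality features, labels them from the ground-truth
#' channel SNR, and balances the classes by random downsampling.
#'
#' @param n_recordings Number of simulated recordings.
#' @param duration Duration of each recording in seconds.
#' @param seed Integer seed (recording `i` uses `seed + i`).
#' @param threshold Labelling SNR threshold in dB.
#' @param balance Balance the classes by downsampling the majority.
#' @return A labelled feature table (data frame).
#' @export
build_training_set <- function(n_recordings = 10, duration = 30, seed = 1L,
                               threshold = 5, balance = TRUE) {
  tables <- lapply(seq_len(n_recordings), function(i) {
    cfg <- study_recording_config(seed + i, duration = duration)
    sim <- generate_recording(cfg)
    tbl <- sqi_feature_table(sim$recording, preset = "train",
                             recording_id = sprintf("sim%03d", i))
    label_from_truth(tbl, sim$truth, threshold)
  })
  out <- do.call(rbind, tables)
  if (balance) out <- balance_dataset(out, seed = seed)
  out
}

#' Score fetal QRS detection on one recording under a channel set
#'
#' Extracts the fetal ECG of every listed abdominal channel with the
#' QRD-RLS canceller, detects fetal R-peaks on each estimate, matches them
#' against the ground-truth fetal peaks within the tolerance window, and
#' micro-averages (sums) the counts over the channels. Peaks inside the
#' adaptive filter's start-up transient are excluded from scoring.
#'
#' @param rec A preprocessed [mc_recording()] with reference channels.
#' @param channels Abdominal channel indices to evaluate; empty yields
#'   zero counts with `FN` equal to the number of reference peaks.
#' @param fetal_peaks Ground-truth fetal peak indices (0-based, at the
#'   recording's rate).
#' @param extractor An [extractor_config()].
#' @param detector A [detector_config()].
#' @param tolerance_ms Matching tolerance.
#' @return A [detection_metrics()] score (micro-averaged counts).
#' @export
score_detection <- function(rec, channels, fetal_peaks,
                            extractor = extractor_config(),
                            detector = detector_config(),
                            tolerance_ms = 50) {
  if (length(channels) == 0) {
    return(detection_metrics(c(TP = 0, FP = 0, FN = length(fetal_peaks))))
  }
  est <- extract_fecg(rec, channels, extractor)
  counts <- c(TP = 0L, FP = 0L, FN = 0L)
  for (e in est) {
    det <- maxsearch_detect(e, detector)
    keep_det <- det$indices >= e$transient
    det <- peak_annotations(det$indices[keep_det], fs = det$fs,
                            label = "fetal")
    ref_idx <- fetal_peaks[fetal_peaks >= e$transient]
    ref <- peak_annotations(ref_idx, fs = rec$fs, label = "fetal")
    counts <- counts + match_peaks(det, ref, tolerance_ms)
  }
  detection_metrics(counts)
}

#' End-to-end evaluation of the channel-selection approach
#'
#' Simulates an evaluation cohort, applies the trained classifier to each
#' recording, and scores fetal QRS detection per recording twice: over all
#' abdominal channels and over the selected channels only. Returns the
#' per-recording metric table, ready for [compare_conditions()].
#'
#' @param model A trained `sqa_model`.
#' @param n_recordings Number of simulated evaluation recordings.
#' @param duration Duration of each recording in seconds.
#' @param seed Integer seed; the cohort is disjoint from any training set
#'   built with a different seed.
#' @param metric Which detection metric to tabulate (default `"F1det"`).
#' @return Data frame with one row per recording: `recording`,
#'   `n_selected`, `all_channels` and `selected_channels` metric values.
#' @export
evaluate_channel_selection <- function(model, n_recordings = 20,
                                       duration = 30, seed = 1000L,
                                       metric = "F1det") {
  rows <- lapply(seq_len(n_recordings), function(i) {
    cfg <- study_recording_config(seed + i, duration = duration)
    sim <- generate_recording(cfg)
    pre <- preprocess_recording(sim$recording, "train")
    abd <- which(pre$channel_roles == "abdominal")
    sel <- select_channels(model, sim$recording, preset = "train")
    s_all <- score_detection(pre, abd, sim$truth$fetal_peaks)
    s_sel <- score_detection(pre, as.integer(sel), sim$truth$fetal_peaks)
    data.frame(recording = i, n_selected = length(sel),
               all_channels = unname(s_all[metric]),
               selected_channels = unname(s_sel[metric]))
  })
  do.call(rbind, rows)
}
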