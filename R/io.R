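#' Multi-channel biopotential recording
#'
#' The central container: a channels-by-samples numeric matrix in microvolt,
#' its sampling frequency, and a role (`"abdominal"` or `"reference"`) per
#' channel. Thoracic reference leads carry the maternal ECG only and feed the
#' adaptive maternal-ECG canceller; abdominal leads are the candidates for
#' selection.
#'
#' @param samples Numeric matrix, channels x samples, microvolt.
#' @param fs Sampling frequency in Hz.
#' @param channel_roles Character vector, one of `"abdominal"`, `"reference"`
#'   per channel; unknown values are an error.
#' @param channel_names Optional channel names.
#' @param meta Free-form named list (e.g. gestational week).
#' @return An object of class `mc_recording`.
#' @export
mc_recording <- function(samples, fs, channel_roles = NULL,
                         channel_names = NULL, meta = list()) {
  if (!is.matrix(samples) || !is.numeric(samples)) {
    stop("`samples` must be a numeric matrix (channels x samples)", call. = FALSE)
  }
  if (nrow(samples) < 1) stop("at least one channel required", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    stop("`fs` must be a positive scalar", call. = FALSE)
  }
  n_ch <- nrow(samples)
  if (is.null(channel_roles)) channel_roles <- rep("abdominal", n_ch)
  if (length(channel_roles) != n_ch ||
      !all(channel_roles %in% c("abdominal", "reference"))) {
    stop("`channel_roles` must be 'abdominal' or 'reference', one per channel",
         call. = FALSE)
  }
  if (is.null(channel_names)) channel_names <- sprintf("CH%02d", seq_len(n_ch))
  stopifnot(length(channel_names) == n_ch)
  structure(list(samples = samples, fs = fs,
                 channel_roles = as.character(channel_roles),
                 channel_names = as.character(channel_names),
                 meta = meta),
            class = "mc_recording")
}

#' @export
print.mc_recording <- function(x, ...) {
  cat(sprintf("<mc_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$samples), ncol(x$samples), x$fs,
              ncol(x$samples) / x$fs))
  cat(sprintf("  abdominal: %d, reference: %d\n",
              sum(x$channel_roles == "abdominal"),
              sum(x$channel_roles == "reference")))
  invisible(x)
}

#' Peak annotations
#'
#' Strictly increasing 0-based sample indices of R-peaks, with their sampling
#' frequency and the annotated heart (`"fetal"` or `"maternal"`).
#'
#' @param indices Integer vector, 0-based, strictly increasing.
#' @param fs Sampling frequency in Hz the indices refer to.
#' @param label `"fetal"` or `"maternal"`.
#' @return An object of class `peak_annotations`.
#' @export
peak_annotations <- function(indices, fs, label = "fetal") {
  indices <- as.integer(indices)
  if (length(indices) > 0 &&
      (any(indices < 0) || any(diff(indices) <= 0))) {
    stop("annotation indices must be non-negative and strictly increasing",
         call. = FALSE)
  }
  stopifnot(fs > 0, label %in% c("fetal", "maternal"))
  structure(list(indices = indices, fs = fs, label = label),
            class = "peak_annotations")
}

#' Write peak annotations as plain text
#'
#' One 0-based sample index per line; the sampling rate and label travel in a
#' `#`-prefixed header line so the file round-trips exactly.
#'
#' @param ann A [peak_annotations()] object.
#' @param path Output file path.
#' @export
write_annotations <- function(ann, path) {
  stopifnot(inherits(ann, "peak_annotations"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%.10g label=%s", ann$fs, ann$label), con)
  if (length(ann$indices) > 0) writeLines(format(ann$indices), con)
  invisible(path)
}

#' Read peak annotations
#'
#' @param path File written by [write_annotations()] (or any file with one
#'   0-based integer index per line).
#' @param fs Sampling rate, required when the file has no header line.
#' @param label Peak label, used when the file has no header line.
#' @return A [peak_annotations()] object.
#' @export
read_annotations <- function(path, fs = NULL, label = "fetal") {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  if (any(hdr)) {
    h <- lines[hdr][1]
    m_fs <- regmatches(h, regexpr("fs=[0-9.eE+-]+", h))
    m_lb <- regmatches(h, regexpr("label=[a-z]+", h))
    if (length(m_fs)) fs <- as.numeric(sub("fs=", "", m_fs))
    if (length(m_lb)) label <- sub("label=", "", m_lb)
  }
  if (is.null(fs)) stop("annotation file has no fs header; supply `fs`",
                        call. = FALSE)
  body <- trimws(lines[!hdr])
  body <- body[nzchar(body)]
  idx <- if (length(body)) as.integer(body) else integer(0)
  if (anyNA(idx)) stop("non-integer annotation line", call. = FALSE)
  if (length(idx) > 1 && any(diff(idx) <= 0)) {
    stop("annotation indices are not strictly increasing", call. = FALSE)
  }
  peak_annotations(idx, fs = fs, label = label)
}

# ---- WFDB-style storage (minimal format-16 subset) -------------------------

#' Write a recording as a WFDB-style record
#'
#' Minimal WFDB format-16 writer: a text `.hea` header and a single
#' little-endian int16 `.dat` file with interleaved samples. Amplitudes are
#' stored with a per-channel gain (ADU per microvolt) chosen to use the int16
#' range, so the round-trip is exact up to that quantisation. The channel
#' role is stored in the signal description field.
#'
#' @param rec An [mc_recording()].
#' @param dir Output directory (created if missing).
#' @param name Record name (basename of the `.hea`/`.dat` pair).
#' @return The path to the `.hea` file, invisibly.
#' @export
write_recording <- function(rec, dir, name = "rec") {
  stopifnot(inherits(rec, "mc_recording"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n_sig <- nrow(rec$samples)
  n_samp <- ncol(rec$samples)
  dat <- paste0(name, ".dat")
  max_abs <- apply(abs(rec$samples), 1, max)
  gain <- ifelse(max_abs > 0, 32000 / max_abs, 200)   # ADU per uV
  adc <- round(rec$samples * gain)
  adc[adc > 32767] <- 32767; adc[adc < -32768] <- -32768
  hdr <- c(sprintf("%s %d %.10g %d", name, n_sig, rec$fs, n_samp),
           sprintf("%s 16 %.10g(0)/uV 16 0 %d 0 0 %s:%s",
                   dat, gain, adc[, 1], rec$channel_roles, rec$channel_names))
  writeLines(hdr, file.path(dir, paste0(name, ".hea")))
  con <- file(file.path(dir, dat), "wb")
  on.exit(close(con))
  writeBin(as.integer(adc), con, size = 2, endian = "little")
  invisible(file.path(dir, paste0(name, ".hea")))
}

read_recording_wfdb <- function(hea_path, role_map = NULL) {
  lines <- readLines(hea_path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(top) < 4) stop("malformed WFDB header", call. = FALSE)
  n_sig <- as.integer(top[2]); fs <- as.numeric(top[3])
  n_samp <- as.integer(top[4])
  if (is.na(fs) || fs <= 0) stop("missing or invalid sampling rate in header",
                                 call. = FALSE)
  sig_lines <- lines[2:(1 + n_sig)]
  parts <- strsplit(trimws(sig_lines), "\\s+")
  dat_file <- vapply(parts, `[[`, "", 1)
  fmt <- vapply(parts, `[[`, "", 2)
  if (any(fmt != "16") || length(unique(dat_file)) != 1) {
    stop("only single-file format-16 records are supported", call. = FALSE)
  }
  gain <- vapply(parts, function(p) {
    as.numeric(sub("\\(.*$", "", p[3]))
  }, numeric(1))
  gain[is.na(gain) | gain == 0] <- 200
  desc <- vapply(parts, function(p) {
    if (length(p) >= 9) paste(p[9:length(p)], collapse = " ") else ""
  }, character(1))
  roles <- rep("abdominal", n_sig)
  names_ <- sprintf("CH%02d", seq_len(n_sig))
  has_role <- grepl("^(abdominal|reference):", desc)
  roles[has_role] <- sub(":.*$", "", desc[has_role])
  names_[has_role] <- sub("^[a-z]+:", "", desc[has_role])
  dat_path <- file.path(dirname(hea_path), dat_file[1])
  con <- file(dat_path, "rb")
  on.exit(close(con))
  raw <- readBin(con, integer(), n = n_sig * n_samp, size = 2,
                 endian = "little", signed = TRUE)
  adc <- matrix(raw, nrow = n_sig)
  samples <- adc / gain
  if (!is.null(role_map)) roles <- role_map
  mc_recording(samples, fs = fs, channel_roles = roles,
               channel_names = names_)
}

read_recording_csv <- function(csv_path, role_map = NULL) {
  sidecar <- sub("\\.csv$", ".json", csv_path)
  if (!file.exists(sidecar)) {
    stop("CSV recording requires a JSON sidecar with fs and roles: ",
         sidecar, call. = FALSE)
  }
  side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(side$fs)) stop("sidecar is missing `fs`", call. = FALSE)
  m <- as.matrix(utils::read.csv(csv_path, header = FALSE))
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("ragged or non-numeric CSV matrix", call. = FALSE)
  roles <- if (!is.null(role_map)) role_map
           else if (!is.null(side$roles)) side$roles
           else rep("abdominal", nrow(m))
  mc_recording(m, fs = side$fs, channel_roles = roles,
               channel_names = side$names %||% NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a multi-channel recording
#'
#' Dispatches on the file type: a WFDB-style `.hea` header (or a directory
#' containing exactly one), or a delimited `.csv` matrix (channels in rows)
#' with a JSON sidecar `{fs, roles, names}` of the same basename. Channels
#' with no declared role default to abdominal. Amplitudes are returned in
#' microvolt.
#'
#' @param path Path to a `.hea` file, a record directory, or a `.csv`.
#' @param role_map Optional character vector overriding the channel roles.
#' @return An [mc_recording()].
#' @export
read_recording <- function(path, role_map = NULL) {
  if (dir.exists(path)) {
    hea <- list.files(path, pattern = "\\.hea$", full.names = TRUE)
    if (length(hea) != 1) {
      stop("directory must contain exactly one .hea record", call. = FALSE)
    }
    return(read_recording_wfdb(hea, role_map))
  }
  if (grepl("\\.hea$", path)) return(read_recording_wfdb(path, role_map))
  if (grepl("\\.csv$", path)) return(read_recording_csv(path, role_map))
  stop("unsupported recording format: ", path, call. = FALSE)
}

#' Write a recording as CSV plus JSON sidecar
#'
#' @param rec An [mc_recording()].
#' @param csv_path Output `.csv` path; the sidecar takes the same basename
#'   with extension `.json`.
#' @export
write_recording_csv <- function(rec, csv_path) {
  stopifnot(inherits(rec, "mc_recording"))
  utils::write.table(rec$samples, csv_path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(
    list(fs = rec$fs, roles = rec$channel_roles, names = rec$channel_names),
    sub("\\.csv$", ".json", csv_path), auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}
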