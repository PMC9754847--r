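#' @keywords internal
"_PACKAGE"

#' Construct an EEG recording object
#'
#' A recording is a channels-by-samples signal block with a shared sampling
#' rate, a position on a per-patient timeline, and a montage tag. All
#' channels must share one sampling rate and one sample count; labels must
#' be unique after canonicalization.
#'
#' @param signals numeric matrix, channels x samples (microvolts or
#'   acquisition units).
#' @param channel_labels character vector, one label per row of `signals`.
#' @param sampling_rate sampling frequency in Hz (positive).
#' @param start_time_sec start of this recording on the patient timeline,
#'   in seconds.
#' @param montage `"bipolar"` (adjacent-electrode differences, e.g.
#'   CHB-MIT-style) or `"referential"` (electrode minus fixed reference).
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(signals, channel_labels, sampling_rate,
                          start_time_sec = 0,
                          montage = c("referential", "bipolar")) {
  montage <- match.arg(montage)
  signals <- as.matrix(signals)
  if (!is.numeric(signals)) stop("signals must be numeric")
  if (length(channel_labels) != nrow(signals))
    stop("channel_labels length must match nrow(signals)")
  if (ncol(signals) < 1L) stop("recording must contain at least one sample")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      sampling_rate <= 0)
    stop("sampling_rate must be a single positive number")
  canon <- canonical_label(channel_labels)
  if (anyDuplicated(canon))
    stop("channel labels are not unique after canonicalization: ",
         paste(unique(canon[duplicated(canon)]), collapse = ", "))
  structure(
    list(channel_labels = as.character(channel_labels),
         sampling_rate = sampling_rate,
         signals = signals,
         start_time_sec = start_time_sec,
         montage = montage),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%s montage)\n",
              nrow(x$signals), ncol(x$signals), x$sampling_rate, x$montage))
  cat(sprintf("  timeline: [%g, %g) s\n", x$start_time_sec,
              x$start_time_sec + ncol(x$signals) / x$sampling_rate))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec an `eeg_recording`.
#' @return length in seconds.
#' @export
recording_duration <- function(rec) ncol(rec$signals) / rec$sampling_rate

#' Canonicalize EEG channel labels
#'
#' Uppercases, strips all whitespace, and removes a trailing `-REF`
#' reference suffix. Bipolar labels keep their `A-B` form. EDF label
#' dialects vary widely; this normalization makes channel specs portable
#' across files.
#'
#' @param x character vector of raw labels.
#' @return character vector of canonical labels.
#' @export
canonical_label <- function(x) {
  x <- toupper(gsub("[[:space:]]+", "", as.character(x)))
  sub("-REF$", "", x)
}

# ---- EDF (European Data Format) ------------------------------------------

edf_ascii <- function(con, n) trimws(rawToChar(readBin(con, "raw", n)))
edf_num <- function(con, n) as.numeric(edf_ascii(con, n))

#' Read an EDF/EDF+ file into a recording
#'
#' Minimal reader for 16-bit EDF: parses the header, checks that all data
#' channels share one sampling rate, and converts digital values to
#' physical units via the per-channel calibration fields. An `EDF
#' Annotations` channel, if present, is dropped.
#'
#' @param path path to an EDF or EDF+ file.
#' @param start_time_sec timeline offset assigned to the recording
#'   (multi-file patients are concatenated by the caller via these offsets).
#' @param montage montage tag to attach (`"bipolar"` or `"referential"`).
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path, start_time_sec = 0,
                     montage = c("referential", "bipolar")) {
  montage <- match.arg(montage)
  if (!file.exists(path)) stop("EDF file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))

  version <- edf_ascii(con, 8L)
  readBin(con, "raw", 80L + 80L + 8L + 8L)       # patient, recording, date, time
  header_bytes <- edf_num(con, 8L)
  readBin(con, "raw", 44L)                        # reserved
  n_records <- edf_num(con, 8L)
  record_sec <- edf_num(con, 8L)
  ns <- edf_num(con, 4L)
  if (is.na(ns) || ns < 1 || is.na(n_records) || is.na(record_sec) ||
      record_sec <= 0)
    stop("unreadable EDF header in ", path)

  labels <- vapply(seq_len(ns), function(i) edf_ascii(con, 16L), "")
  readBin(con, "raw", 80L * ns)                   # transducer
  readBin(con, "raw", 8L * ns)                    # physical dimension
  phys_min <- vapply(seq_len(ns), function(i) edf_num(con, 8L), 0)
  phys_max <- vapply(seq_len(ns), function(i) edf_num(con, 8L), 0)
  dig_min <- vapply(seq_len(ns), function(i) edf_num(con, 8L), 0)
  dig_max <- vapply(seq_len(ns), function(i) edf_num(con, 8L), 0)
  readBin(con, "raw", 80L * ns)                   # prefiltering
  spr <- vapply(seq_len(ns), function(i) edf_num(con, 8L), 0)
  readBin(con, "raw", 32L * ns)                   # reserved

  if (any(is.na(spr)) || any(spr < 1))
    stop("unreadable EDF signal header in ", path)
  expect_header <- 256L + 256L * ns
  if (!is.na(header_bytes) && header_bytes != expect_header)
    stop("corrupt EDF header (header byte count mismatch) in ", path)

  keep <- canonical_label(labels) != "EDFANNOTATIONS"
  if (!any(keep)) stop("EDF file contains no data channels: ", path)
  rates <- spr / record_sec
  if (length(unique(rates[keep])) != 1L)
    stop("unsupported layout: channels with differing sampling rates in ",
         path)

  total_per_record <- sum(spr)
  dat <- readBin(con, "integer", n = total_per_record * n_records,
                 size = 2L, signed = TRUE, endian = "little")
  if (length(dat) < total_per_record * n_records)
    stop("truncated EDF data section in ", path)

  # record-major layout: per record, spr[i] samples of each signal in turn
  offsets <- c(0, cumsum(spr))
  signals <- matrix(0, nrow = sum(keep), ncol = spr[keep][1] * n_records)
  row_i <- 0L
  for (i in seq_len(ns)) {
    if (!keep[i]) next
    row_i <- row_i + 1L
    idx <- as.vector(outer(seq_len(spr[i]) + offsets[i],
                           (seq_len(n_records) - 1L) * total_per_record, "+"))
    dig <- dat[idx]
    gain <- (phys_max[i] - phys_min[i]) / (dig_max[i] - dig_min[i])
    signals[row_i, ] <- (dig - dig_min[i]) * gain + phys_min[i]
  }
  eeg_recording(signals, labels[keep], rates[keep][1],
                start_time_sec = start_time_sec, montage = montage)
}

#' Write a recording as a 16-bit EDF file (test fixture writer)
#'
#' Serializes a recording as plain EDF with one-second data records and a
#' per-channel linear calibration spanning the observed signal range.
#' Intended for building round-trip test fixtures; values are quantized to
#' 16 bits, so reads agree with the source only to the quantization step
#' (range / 65535 per channel).
#'
#' @param rec an [eeg_recording()] whose sampling rate is a positive
#'   integer and whose sample count is a multiple of the sampling rate.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  fs <- rec$sampling_rate
  if (fs != round(fs)) stop("EDF fixture writer requires integer Hz")
  n_samples <- ncol(rec$signals)
  if (n_samples %% fs != 0)
    stop("sample count must be a whole number of 1-second records")
  n_records <- n_samples %/% fs
  ns <- nrow(rec$signals)

  pmin_ <- apply(rec$signals, 1, min)
  pmax_ <- apply(rec$signals, 1, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmin_[flat] <- pmin_[flat] - 1
  pmax_[flat] <- pmax_[flat] + 1
  dmin <- -32768; dmax <- 32767

  pad <- function(x, n) {
    x <- as.character(x)
    x <- substr(x, 1L, n)
    formatC(x, width = n, flag = "-")
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(pad("0", 8), pad("fixture", 80), pad("fixture", 80),
                   pad("01.01.26", 8), pad("00.00.00", 8),
                   pad(256 + 256 * ns, 8), pad("", 44),
                   pad(n_records, 8), pad(1, 8), pad(ns, 4)),
            con, eos = NULL)
  field <- function(vals, n)
    writeChar(paste(vapply(vals, pad, "", n = n), collapse = ""), con,
              eos = NULL)
  field(rec$channel_labels, 16)
  field(rep("", ns), 80)
  field(rep("uV", ns), 8)
  field(formatC(pmin_, digits = 6, format = "g"), 8)
  field(formatC(pmax_, digits = 6, format = "g"), 8)
  field(rep(dmin, ns), 8)
  field(rep(dmax, ns), 8)
  field(rep("", ns), 80)
  field(rep(fs, ns), 8)
  field(rep("", ns), 32)

  gain <- (pmax_ - pmin_) / (dmax - dmin)
  dig <- round((rec$signals - pmin_) / gain + dmin)
  dig[dig < dmin] <- dmin; dig[dig > dmax] <- dmax
  for (r in seq_len(n_records)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    writeBin(as.integer(t(dig[, cols, drop = FALSE])), con, size = 2L,
             endian = "little")
  }
  invisible(path)
}

# ---- channel selection ---------------------------------------------------

#' Built-in channel-spec presets
#'
#' `"chbmit21"` is the 21-signal bipolar longitudinal montage shared by the
#' CHB-MIT-style recordings; `"fhpku19"` is the 19-electrode referential
#' 10-20 set. Presets are starting points: pass any custom character vector
#' to [select_channels()] instead.
#'
#' @param name `"chbmit21"` or `"fhpku19"`.
#' @return character vector of canonical channel labels.
#' @export
channel_preset <- function(name = c("chbmit21", "fhpku19")) {
  name <- match.arg(name)
  switch(name,
    chbmit21 = c("FP1-F7", "F7-T7", "T7-P7", "P7-O1",
                 "FP1-F3", "F3-C3", "C3-P3", "P3-O1",
                 "FP2-F4", "F4-C4", "C4-P4", "P4-O2",
                 "FP2-F8", "F8-T8", "T8-P8", "P8-O2",
                 "FZ-CZ", "CZ-PZ", "T7-FT9", "FT9-FT10", "FT10-T8"),
    fhpku19 = c("FP1", "FP2", "F3", "F4", "C3", "C4", "P3", "P4",
                "O1", "O2", "F7", "F8", "T3", "T4", "T5", "T6",
                "FZ", "CZ", "PZ"))
}

#' Restrict a recording to a canonical, ordered channel set
#'
#' Keeps exactly the requested channels, in the requested order, matching
#' labels after [canonical_label()] normalization. A fixed channel order
#' makes edge indices comparable across epochs and recordings.
#'
#' @param rec an [eeg_recording()].
#' @param channel_spec character vector of canonical labels (e.g. a
#'   [channel_preset()]).
#' @return An [eeg_recording()] with `length(channel_spec)` channels.
#' @export
select_channels <- function(rec, channel_spec) {
  want <- canonical_label(channel_spec)
  have <- canonical_label(rec$channel_labels)
  if (anyDuplicated(have)) {
    warning("duplicate canonical channel labels; keeping first occurrence")
    first <- !duplicated(have)
    rec$signals <- rec$signals[first, , drop = FALSE]
    rec$channel_labels <- rec$channel_labels[first]
    have <- have[first]
  }
  idx <- match(want, have)
  if (anyNA(idx))
    stop("requested channels missing from recording: ",
         paste(want[is.na(idx)], collapse = ", "))
  eeg_recording(rec$signals[idx, , drop = FALSE], want,
                rec$sampling_rate, rec$start_time_sec, rec$montage)
}

# ---- seizure annotations -------------------------------------------------

#' Construct a seizure annotation set
#'
#' Events live on the same per-patient timeline as the recordings'
#' `start_time_sec`. Events must be strictly positive-length, sorted and
#' non-overlapping.
#'
#' @param onset_sec,offset_sec numeric vectors of equal length; seizure k
#'   spans `[onset_sec[k], offset_sec[k])`.
#' @return An object of class `seizure_annotation` (a data frame with
#'   columns `onset_sec`, `offset_sec`).
#' @export
seizure_annotation <- function(onset_sec = numeric(), offset_sec = numeric()) {
  if (length(onset_sec) != length(offset_sec))
    stop("onset_sec and offset_sec must have equal length")
  o <- order(onset_sec)
  onset_sec <- as.numeric(onset_sec[o]); offset_sec <- as.numeric(offset_sec[o])
  if (any(onset_sec >= offset_sec))
    stop("every seizure must satisfy onset_sec < offset_sec")
  if (length(onset_sec) > 1 &&
      any(onset_sec[-1] < offset_sec[-length(offset_sec)]))
    stop("seizure events must not overlap")
  structure(data.frame(onset_sec = onset_sec, offset_sec = offset_sec),
            class = c("seizure_annotation", "data.frame"))
}

#' Read seizure annotations from CSV
#'
#' Expects a header with columns `onset_sec` and `offset_sec`; an empty
#' body yields an empty annotation (an all-interictal candidate recording).
#' Converters from dataset-specific formats (e.g. CHB-MIT summary files)
#' are a user task upstream of this CSV.
#'
#' @param path path to the annotation CSV.
#' @return A [seizure_annotation()].
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  df <- utils::read.csv(path)
  if (!all(c("onset_sec", "offset_sec") %in% names(df)))
    stop("annotation CSV must have columns onset_sec, offset_sec")
  seizure_annotation(df$onset_sec, df$offset_sec)
}
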