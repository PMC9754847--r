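# Interval helpers: intervals are 2-column matrices (start, end), half-open
# [start, end), kept sorted and disjoint.

iv_mat <- function(starts, ends) {
  m <- cbind(start = as.numeric(starts), end = as.numeric(ends))
  m[m[, 1] < m[, 2], , drop = FALSE]
}

iv_subtract <- function(base, cut) {
  # base minus union(cut); both 2-col matrices
  if (nrow(base) == 0) return(base)
  if (nrow(cut) == 0) return(base)
  cut <- cut[order(cut[, 1]), , drop = FALSE]
  out <- NULL
  for (i in seq_len(nrow(base))) {
    lo <- base[i, 1]; hi <- base[i, 2]
    pos <- lo
    for (j in seq_len(nrow(cut))) {
      cs <- cut[j, 1]; ce <- cut[j, 2]
      if (ce <= pos || cs >= hi) next
      if (cs > pos) out <- rbind(out, c(pos, cs))
      pos <- max(pos, ce)
      if (pos >= hi) break
    }
    if (pos < hi) out <- rbind(out, c(pos, hi))
  }
  if (is.null(out)) iv_mat(numeric(), numeric()) else
    iv_mat(out[, 1], out[, 2])
}

iv_intersect_window <- function(m, lo, hi) {
  if (nrow(m) == 0) return(m)
  iv_mat(pmax(m[, 1], lo), pmin(m[, 2], hi))
}

#' Label preictal / interictal / excluded intervals of a recording
#'
#' Applies the state-definition rules used throughout the package:
#' \itemize{
#'   \item the preictal (case) state is the `preictal_minutes` window
#'     immediately before each retained seizure onset, clipped to the
#'     recording and to the end of any earlier exclusion;
#'   \item the ictal span itself is excluded;
#'   \item the `postictal_hours` window after each retained seizure offset
#'     is excluded, to keep postictal activity out of the control class;
#'   \item a seizure whose onset falls less than `postictal_hours` after
#'     the previous retained seizure's offset is dropped entirely (only the
#'     first of a close-spaced pair is used), its ictal span still excluded;
#'   \item everything else is interictal (control).
#' }
#'
#' @param ann a [seizure_annotation()]; events must lie within the window.
#' @param rec_start_sec,rec_end_sec recording window on the patient
#'   timeline, seconds.
#' @param preictal_minutes length of the preictal window (default 30).
#' @param postictal_hours length of the postictal exclusion and the minimum
#'   inter-seizure gap (default 2).
#' @return An object of class `state_intervals`: lists `preictal`,
#'   `interictal`, `excluded` of (start, end) matrices, plus
#'   `excluded_reason` tags (`"ictal"`, `"postictal"`,
#'   `"short-gap-seizure"`) and the indices of `dropped_seizures`.
#' @export
label_states <- function(ann, rec_start_sec, rec_end_sec,
                         preictal_minutes = 30, postictal_hours = 2) {
  stopifnot(rec_end_sec > rec_start_sec)
  pre_sec <- preictal_minutes * 60
  post_sec <- postictal_hours * 3600
  n_ev <- nrow(ann)
  if (n_ev > 0 &&
      (min(ann$onset_sec) < rec_start_sec || max(ann$offset_sec) > rec_end_sec))
    stop("annotation events must lie within [rec_start_sec, rec_end_sec]")

  retained <- logical(n_ev)
  last_off <- -Inf
  for (k in seq_len(n_ev)) {
    if (ann$onset_sec[k] - last_off >= post_sec || !is.finite(last_off)) {
      retained[k] <- TRUE
      last_off <- ann$offset_sec[k]
    }
  }

  ex_start <- numeric(); ex_end <- numeric(); ex_reason <- character()
  for (k in seq_len(n_ev)) {
    if (retained[k]) {
      ex_start <- c(ex_start, ann$onset_sec[k], ann$offset_sec[k])
      ex_end <- c(ex_end, ann$offset_sec[k],
                  min(ann$offset_sec[k] + post_sec, rec_end_sec))
      ex_reason <- c(ex_reason, "ictal", "postictal")
    } else {
      ex_start <- c(ex_start, ann$onset_sec[k])
      ex_end <- c(ex_end, ann$offset_sec[k])
      ex_reason <- c(ex_reason, "short-gap-seizure")
    }
  }
  keep <- ex_start < ex_end
  excluded <- iv_mat(ex_start[keep], ex_end[keep])
  ex_reason <- ex_reason[keep]

  pre_start <- numeric(); pre_end <- numeric(); truncated <- logical()
  for (k in which(retained)) {
    onset <- ann$onset_sec[k]
    lo <- max(onset - pre_sec, rec_start_sec)
    if (nrow(excluded) > 0) {
      clash <- excluded[, 1] < onset & excluded[, 2] > lo &
        !(excluded[, 1] == onset)           # the seizure's own ictal span
      if (any(clash)) lo <- max(lo, min(max(excluded[clash, 2]), onset))
    }
    if (lo < onset) {
      pre_start <- c(pre_start, lo)
      pre_end <- c(pre_end, onset)
      truncated <- c(truncated, onset - lo < pre_sec)
    }
  }
  preictal <- iv_mat(pre_start, pre_end)

  inter <- iv_subtract(iv_mat(rec_start_sec, rec_end_sec),
                       rbind(preictal, excluded))

  structure(list(preictal = preictal,
                 interictal = inter,
                 excluded = excluded,
                 excluded_reason = ex_reason,
                 preictal_truncated = truncated,
                 dropped_seizures = which(!retained),
                 preictal_minutes = preictal_minutes,
                 postictal_hours = postictal_hours),
            class = "state_intervals")
}

#' @export
print.state_intervals <- function(x, ...) {
  tot <- function(m) if (nrow(m)) sum(m[, 2] - m[, 1]) else 0
  cat(sprintf("<state_intervals> preictal %g s (%d), interictal %g s (%d), excluded %g s (%d)\n",
              tot(x$preictal), nrow(x$preictal),
              tot(x$interictal), nrow(x$interictal),
              tot(x$excluded), nrow(x$excluded)))
  if (length(x$dropped_seizures))
    cat("  dropped close-spaced seizures: ",
        paste(x$dropped_seizures, collapse = ", "), "\n")
  invisible(x)
}

new_epoch <- function(data, label, patient_id, epoch_index, origin_sec) {
  structure(list(data = data, label = as.integer(label),
                 patient_id = patient_id, epoch_index = as.integer(epoch_index),
                 origin_sec = origin_sec),
            class = "eeg_epoch")
}

new_epoch_set <- function(epochs, channel_labels) {
  labs <- vapply(epochs, function(e) e$label, 0L)
  structure(list(epochs = epochs,
                 n1 = sum(labs == 1L), n2 = sum(labs == 0L),
                 channel_labels = channel_labels),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  p <- if (length(x$epochs)) nrow(x$epochs[[1]]$data) else 0
  q <- if (length(x$epochs)) ncol(x$epochs[[1]]$data) else 0
  cat(sprintf("<epoch_set> %d epochs (%d preictal, %d interictal), p = %d, q = %d\n",
              length(x$epochs), x$n1, x$n2, p, q))
  invisible(x)
}

#' Number of epochs an interval set will yield
#'
#' The count identity used by the extraction tests: each interval
#' contributes `floor(length / epoch_seconds)` nonoverlapping epochs.
#'
#' @param intervals a (start, end) matrix.
#' @param epoch_seconds epoch length in seconds.
#' @return integer epoch count.
#' @export
count_epochs <- function(intervals, epoch_seconds = 60) {
  if (nrow(intervals) == 0) return(0L)
  sum(floor((intervals[, 2] - intervals[, 1]) / epoch_seconds))
}

#' Extract labeled, per-second-averaged epochs from a recording
#'
#' Tiles each preictal and interictal interval left-to-right with
#' nonoverlapping `epoch_seconds` windows (partial trailing windows are
#' discarded, never padded). Within a window every consecutive 1-second
#' block of `sampling_rate` samples is averaged per channel, so an epoch is
#' a p x `epoch_seconds` matrix of per-second mean amplitudes. Intervals
#' are first clipped to the span actually covered by `rec`.
#'
#' @param rec an [eeg_recording()] with integer samples-per-second.
#' @param intervals a [label_states()] result on the same timeline.
#' @param epoch_seconds epoch length (default 60 s).
#' @param patient_id identifier stored on each epoch.
#' @return An `epoch_set`: epochs with binary labels (1 preictal,
#'   0 interictal), plus counts `n1`, `n2`.
#' @export
extract_epochs <- function(rec, intervals, epoch_seconds = 60,
                           patient_id = "patient") {
  fs <- rec$sampling_rate
  if (abs(fs - round(fs)) > 1e-9)
    stop("sampling_rate must be an integer number of samples per second")
  fs <- as.integer(round(fs))
  rec_lo <- rec$start_time_sec
  rec_hi <- rec$start_time_sec + ncol(rec$signals) / fs
  # per-second block averager: (fs * epoch_seconds) x epoch_seconds
  agg <- kronecker(diag(epoch_seconds), rep(1 / fs, fs))

  epochs <- list(); idx <- 0L
  for (cls in c("preictal", "interictal")) {
    lab <- if (cls == "preictal") 1L else 0L
    m <- iv_intersect_window(intervals[[cls]], rec_lo, rec_hi)
    for (i in seq_len(nrow(m))) {
      n_ep <- floor((m[i, 2] - m[i, 1]) / epoch_seconds)
      if (n_ep < 1) next
      for (e in seq_len(n_ep)) {
        s0 <- m[i, 1] + (e - 1) * epoch_seconds
        c0 <- round((s0 - rec_lo) * fs)
        block <- rec$signals[, (c0 + 1):(c0 + fs * epoch_seconds),
                             drop = FALSE]
        idx <- idx + 1L
        epochs[[idx]] <- new_epoch(block %*% agg, lab, patient_id, idx, s0)
      }
    }
  }
  new_epoch_set(epochs, rec$channel_labels)
}

#' Write an epoch set as plain-text files
#'
#' Writes `manifest.csv` (columns `patient_id`, `epoch_index`, `label`,
#' `origin_sec` -- the public contract) and `signals.csv` (long-by-channel
#' wide-by-second data) into `dir`.
#'
#' @param es an `epoch_set`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_epoch_set <- function(es, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- data.frame(
    patient_id = vapply(es$epochs, function(e) e$patient_id, ""),
    epoch_index = vapply(es$epochs, function(e) e$epoch_index, 0L),
    label = vapply(es$epochs, function(e) e$label, 0L),
    origin_sec = vapply(es$epochs, function(e) e$origin_sec, 0))
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  sig <- do.call(rbind, lapply(es$epochs, function(e) {
    data.frame(epoch_index = e$epoch_index,
               channel = es$channel_labels,
               e$data, check.names = FALSE)
  }))
  names(sig)[-(1:2)] <- paste0("t", seq_len(ncol(sig) - 2L))
  utils::write.csv(sig, file.path(dir, "signals.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read an epoch set written by [write_epoch_set()]
#' @param dir directory containing `manifest.csv` and `signals.csv`.
#' @return An `epoch_set`.
#' @export
read_epoch_set <- function(dir) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"))
  sig <- utils::read.csv(file.path(dir, "signals.csv"), check.names = FALSE)
  channels <- unique(sig$channel)
  epochs <- lapply(seq_len(nrow(man)), function(i) {
    rows <- sig[sig$epoch_index == man$epoch_index[i], , drop = FALSE]
    rows <- rows[match(channels, rows$channel), , drop = FALSE]
    dat <- as.matrix(rows[, -(1:2), drop = FALSE])
    dimnames(dat) <- NULL
    new_epoch(dat, man$label[i], man$patient_id[i], man$epoch_index[i],
              man$origin_sec[i])
  })
  new_epoch_set(epochs, as.character(channels))
}
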