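#' Average-reference and band-pass filter a recording
#'
#' Applies the study's acquisition conventions: the instantaneous mean across
#' the 19 channels is subtracted from every sample (average reference), then
#' each channel is band-pass filtered with a 4th-order Butterworth applied
#' forward-backward (zero phase). Re-referencing is idempotent; common-mode
#' activity is removed exactly.
#'
#' @param rec an [eeg_recording()].
#' @param band pass band in Hz; the upper edge is clipped below Nyquist.
#' @param rereference apply the average reference (default TRUE).
#' @return A filtered [eeg_recording()].
#' @export
preprocess <- function(rec, band = c(1, 100), rereference = TRUE) {
  stopifnot(inherits(rec, "eeg_recording"))
  x <- rec$samples
  if (rereference) x <- x - rowMeans(x)
  nyq <- rec$sampling_rate / 2
  hi <- min(band[2], 0.99 * nyq)
  bf <- signal::butter(2, c(band[1], hi) / nyq, type = "pass")  # order-4 band-pass
  for (j in seq_len(ncol(x))) x[, j] <- signal::filtfilt(bf, x[, j])
  out <- rec
  out$samples <- x
  out
}

#' Read an artifact annotation table
#'
#' Plain-text delimited table with columns `start_hour` and `include`
#' (logical or 0/1); epochs whose start hour appears with `include = FALSE`
#' are flagged excluded by [schedule_epochs()].
#'
#' @param path file path (comma- or whitespace-delimited, header required).
#' @return data.frame with numeric `start_hour` and logical `include`.
#' @export
read_artifact_annotations <- function(path) {
  df <- utils::read.table(path, header = TRUE,
                          sep = if (grepl("\\.csv$", path)) "," else "")
  if (!all(c("start_hour", "include") %in% names(df)))
    .stopf("annotation table needs columns start_hour, include")
  df$start_hour <- as.numeric(df$start_hour)
  df$include <- as.logical(df$include)
  df
}

#' Build the clinical epoch schedule for a recording
#'
#' One 300-s epoch per hour of registration through 48 h after the arrest,
#' then one epoch every 2 h. Each epoch occupies the first 300 s of its slot
#' and must lie wholly within the recording; a recording shorter than one
#' epoch yields an empty schedule. Epochs whose start hour is marked
#' `include = FALSE` in the annotation table are flagged excluded (artifact).
#'
#' @param rec an [eeg_recording()] with a valid `t0_offset`.
#' @param annotations optional data.frame from [read_artifact_annotations()].
#' @param epoch_s epoch length in seconds.
#' @return data.frame with `start_hour` (since arrest), `rel_start_s`
#'   (seconds into the recording) and logical `included`.
#' @export
schedule_epochs <- function(rec, annotations = NULL, epoch_s = 300) {
  stopifnot(inherits(rec, "eeg_recording"))
  dur <- recording_duration(rec)
  t0 <- rec$t0_offset
  end_h <- t0 + dur / 3600
  hours <- c(0:47, seq(48, max(48, ceiling(end_h)), by = 2))
  hours <- unique(hours)
  rel <- (hours - t0) * 3600
  ok <- rel >= 0 & (rel + epoch_s) <= dur + 1e-9
  hours <- hours[ok]; rel <- rel[ok]
  included <- rep(TRUE, length(hours))
  if (!is.null(annotations)) {
    bad <- annotations$start_hour[!annotations$include]
    included[hours %in% bad] <- FALSE
  }
  data.frame(start_hour = hours, rel_start_s = rel, included = included)
}

#' Extract one epoch from a recording
#'
#' @param rec an [eeg_recording()].
#' @param rel_start_s epoch start in seconds from the beginning of the
#'   recording.
#' @param epoch_s epoch length in seconds.
#' @return An [eeg_recording()] slice whose `t0_offset` is the epoch start in
#'   hours since arrest.
#' @export
extract_epoch <- function(rec, rel_start_s, epoch_s = 300) {
  fs <- rec$sampling_rate
  i0 <- round(rel_start_s * fs)
  n <- round(epoch_s * fs)
  if (i0 + n > nrow(rec$samples))
    .stopf("epoch [%g, %g) s exceeds the recording", rel_start_s,
           rel_start_s + epoch_s)
  out <- rec
  out$samples <- rec$samples[(i0 + 1):(i0 + n), , drop = FALSE]
  out$t0_offset <- rec$t0_offset + rel_start_s / 3600
  out
}
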