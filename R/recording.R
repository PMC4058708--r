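#' Multichannel EEG recording
#'
#' Container for a 19-channel scalp EEG in microvolts. Samples are stored as
#' a numeric matrix with one column per channel, columns named and ordered by
#' the 10-20 montage ([montage_1020()]).
#'
#' @param samples numeric matrix, samples x channels, in microvolts; column
#'   names must be montage labels.
#' @param sampling_rate sampling rate in Hz.
#' @param t0_offset recording start in hours since the (cardiac) arrest.
#' @return Object of class `eeg_recording` with fields `samples`,
#'   `sampling_rate`, `channel_labels`, `t0_offset`.
#' @export
eeg_recording <- function(samples, sampling_rate = 256, t0_offset = 0) {
  if (!is.matrix(samples) || !is.numeric(samples))
    .stopf("samples must be a numeric matrix (samples x channels)")
  labs <- colnames(samples)
  if (is.null(labs)) .stopf("samples must have channel labels as column names")
  missing <- setdiff(montage_1020(), labs)
  if (length(missing) > 0L)
    .stopf("missing montage channel(s): %s", paste(missing, collapse = ", "))
  samples <- samples[, montage_1020(), drop = FALSE]
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 channel_labels = montage_1020(), t0_offset = t0_offset),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels, %.1f s at %g Hz, t0 + %g h\n",
              ncol(x$samples), nrow(x$samples) / x$sampling_rate,
              x$sampling_rate, x$t0_offset))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec an [eeg_recording()].
#' @return Seconds of signal.
#' @export
recording_duration <- function(rec) nrow(rec$samples) / rec$sampling_rate
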