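# Minimal EDF/EDF+ support: 16-bit little-endian samples, ASCII headers.
# Covers what ICU EEG exports need (uniform sampling, uV signals); written
# in-package because no installed R library reads EDF.

.edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)  # left-justified, space padded
}

.edf_num <- function(x, width = 8) .edf_pad(format(x, trim = TRUE), width)

#' Write a recording to an EDF file
#'
#' Emits a plain EDF file with one-second data records, digital range
#' -32768..32767 mapped to -327.68..327.67 uV (0.01 uV/bit). The recording's
#' offset from arrest is stored in the recording-identification field as
#' `t0_hours=<value>` so that [read_recording()] round-trips it.
#'
#' @param rec an [eeg_recording()].
#' @param path output file path.
#' @param patient_id free-text patient identification (80 chars max).
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, patient_id = "X") {
  stopifnot(inherits(rec, "eeg_recording"))
  .write_edf_core(rec$samples, rec$channel_labels, rec$sampling_rate, path,
                  patient_id = patient_id,
                  recording_id = sprintf("t0_hours=%g", rec$t0_offset))
}

# generic EDF writer core: any channel set / labels
.write_edf_core <- function(samples, labels, fs, path, patient_id = "X",
                            recording_id = "") {
  if (fs != round(fs)) .stopf("EDF writer requires an integer sampling rate")
  ns <- ncol(samples)
  n_rec <- floor(nrow(samples) / fs)
  if (n_rec < 1) .stopf("recording shorter than one 1-s data record")
  x <- samples[seq_len(n_rec * fs), , drop = FALSE]

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, eos = NULL)
  wr(.edf_pad("0", 8))
  wr(.edf_pad(patient_id, 80))
  wr(.edf_pad(recording_id, 80))
  wr(.edf_pad("01.01.00", 8))
  wr(.edf_pad("00.00.00", 8))
  wr(.edf_num(256 * (ns + 1)))
  wr(.edf_pad("", 44))
  wr(.edf_num(n_rec))
  wr(.edf_num(1))
  wr(.edf_num(ns, 4))
  for (lab in labels) wr(.edf_pad(paste("EEG", lab), 16))
  for (i in seq_len(ns)) wr(.edf_pad("AgAgCl electrode", 80))
  for (i in seq_len(ns)) wr(.edf_pad("uV", 8))
  for (i in seq_len(ns)) wr(.edf_num(-327.68))
  for (i in seq_len(ns)) wr(.edf_num(327.67))
  for (i in seq_len(ns)) wr(.edf_num(-32768))
  for (i in seq_len(ns)) wr(.edf_num(32767))
  for (i in seq_len(ns)) wr(.edf_pad("", 80))
  for (i in seq_len(ns)) wr(.edf_num(fs))
  for (i in seq_len(ns)) wr(.edf_pad("", 32))

  dig <- round(x / 0.01)
  dig[dig > 32767] <- 32767
  dig[dig < -32768] <- -32768
  # sample-major within channel, channel-major within record
  arr <- array(as.integer(dig), dim = c(fs, n_rec, ns))
  writeBin(as.integer(aperm(arr, c(1, 3, 2))), con, size = 2,
           endian = "little")
  invisible(path)
}

# Parse an EDF file into raw signals + header. Internal.
.read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) {
    s <- readChar(con, w, useBytes = TRUE)
    if (length(s) == 0) .stopf("not a valid EDF file (truncated header): %s", path)
    trimws(s)
  }
  version <- rd(8)
  if (version != "0") .stopf("not a valid EDF file (version '%s'): %s", version, path)
  patient <- rd(80); recording_id <- rd(80)
  rd(8); rd(8)                     # start date / time, unused
  rd(8)                            # header bytes
  reserved <- rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) .stopf("not a valid EDF file (bad signal count): %s", path)
  field <- function(w) vapply(seq_len(ns), function(i) rd(w), character(1))
  labels <- field(16)
  field(80)                        # transducer
  dims <- field(8)
  pmin <- as.numeric(field(8)); pmax <- as.numeric(field(8))
  dmin <- as.numeric(field(8)); dmax <- as.numeric(field(8))
  field(80)                        # prefiltering
  spr <- as.integer(field(8))
  field(32)
  total <- sum(spr) * n_rec
  raw <- readBin(con, integer(), n = total, size = 2, endian = "little",
                 signed = TRUE)
  if (length(raw) != total)
    .stopf("EDF data shorter than header declares: %s", path)
  offs <- c(0L, cumsum(spr))
  block <- sum(spr)
  signals <- lapply(seq_len(ns), function(c) {
    idx <- as.vector(outer(seq_len(spr[c]) + offs[c],
                           (seq_len(n_rec) - 1L) * block, `+`))
    slope <- (pmax[c] - pmin[c]) / (dmax[c] - dmin[c])
    (raw[idx] - dmin[c]) * slope + pmin[c]
  })
  list(labels = labels, signals = signals, fs = spr / rec_dur,
       dims = dims, recording_id = recording_id, patient = patient,
       edf_plus = grepl("^EDF\\+", reserved))
}

#' Read an EEG recording from an EDF/EDF+ file
#'
#' Reads the file, normalizes channel labels to the 10-20 montage (handling
#' common aliases such as T7 for T3 and "EEG "/reference suffixes), keeps the
#' 19 analysis channels, and resamples to 256 Hz if the source rate differs
#' (polyphase resampling via the signal package). Signals are returned in
#' microvolts. Errors name any missing montage channel.
#'
#' @param path EDF file path.
#' @param t0_offset hours since arrest at recording start; if `NULL`, parsed
#'   from a `t0_hours=` token in the recording-identification field (0 when
#'   absent).
#' @param target_fs analysis sampling rate, Hz.
#' @return An [eeg_recording()].
#' @export
read_recording <- function(path, t0_offset = NULL, target_fs = 256) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  edf <- .read_edf(path)
  labs <- normalize_labels(edf$labels)
  keep <- match(montage_1020(), labs)
  missing <- montage_1020()[is.na(keep)]
  if (length(missing) > 0L)
    .stopf("montage error: missing channel(s) %s", paste(missing, collapse = ", "))
  fs <- edf$fs[keep]
  if (length(unique(fs)) != 1L)
    .stopf("analysis channels have differing sampling rates")
  fs <- fs[1]
  sig <- edf$signals[keep]
  if (fs != target_fs) {
    frac <- .rat(target_fs / fs)
    sig <- lapply(sig, function(s) signal::resample(s, frac[1], frac[2]))
    fs <- target_fs
  }
  samples <- do.call(cbind, sig)
  colnames(samples) <- montage_1020()
  if (is.null(t0_offset)) {
    m <- regmatches(edf$recording_id,
                    regexpr("t0_hours=[-0-9.eE+]+", edf$recording_id))
    t0_offset <- if (length(m)) as.numeric(sub("t0_hours=", "", m)) else 0
  }
  eeg_recording(samples, sampling_rate = fs, t0_offset = t0_offset)
}

# small rational approximation for resampling ratios
.rat <- function(x, max_den = 1000) {
  den <- seq_len(max_den)
  num <- round(x * den)
  i <- which.min(abs(num / den - x))
  c(num[i], den[i])
}
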