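#' Per-second amplitude spectra of an epoch
#'
#' Short-time Fourier analysis on the clinical grid: 2-s Hann-tapered windows
#' starting every second (50% overlap), giving a 0.5 Hz frequency resolution.
#' Amplitudes are moduli of the Fourier coefficients, scaled so a pure
#' sinusoid of amplitude A at an exact grid frequency reads A (in uV).
#' Bins cover 0-26 Hz so every bin of the 1-25 Hz analysis range has four
#' spectral neighbours for the peak criteria.
#'
#' @param rec an [eeg_recording()] epoch (any duration >= 2 s; the clinical
#'   epoch is 300 s giving 299 windows).
#' @param fmax_margin_hz highest retained frequency (must exceed 25 Hz by at
#'   least two bins).
#' @return Object of class `epoch_spectra`: list with `amplitudes`
#'   (window x channel x bin array), `freqs` (bin centres, Hz) and
#'   `window_starts` (s).
#' @export
windowed_spectra <- function(rec, fmax_margin_hz = 26) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$sampling_rate
  N <- 2L * fs                       # 2-s window: 0.5 Hz bins
  x <- rec$samples
  if (nrow(x) < N) .stopf("epoch shorter than one 2-s analysis window")
  n_win <- floor((nrow(x) - N) / fs) + 1L
  w <- 0.5 * (1 - cos(2 * pi * (0:(N - 1)) / N))   # periodic Hann
  scale <- 2 / sum(w)
  n_bins <- round(fmax_margin_hz / 0.5) + 1L
  freqs <- (seq_len(n_bins) - 1L) * 0.5
  amps <- array(NA_real_, dim = c(n_win, ncol(x), n_bins),
                dimnames = list(NULL, colnames(x), freqs))
  for (t in seq_len(n_win)) {
    seg <- x[((t - 1L) * fs + 1L):((t - 1L) * fs + N), , drop = FALSE] * w
    co <- stats::mvfft(seg)[seq_len(n_bins), , drop = FALSE]
    amps[t, , ] <- t(Mod(co)) * scale
  }
  structure(list(amplitudes = amps, freqs = freqs,
                 window_starts = seq_len(n_win) - 1),
            class = "epoch_spectra")
}

#' Peak-significance criteria configuration
#'
#' The three published criteria are relative: a frequency bin is significant
#' when (a) its amplitude is at least `ratio_local` of the maximum of that
#' same frequency over the surrounding `2*neighborhood_s` seconds, (b) at
#' least `ratio_max` of the largest amplitude in the window over 1-25 Hz, and
#' (c) strictly larger than its four spectral neighbours (+-0.5, +-1.0 Hz).
#' `amplitude_floor` adds an optional absolute threshold in uV (0 disables
#' it, matching the published, purely relative criteria).
#'
#' @param ratio_local criterion (a) fraction; default 0.05.
#' @param ratio_max criterion (b) fraction; default 0.50.
#' @param neighborhood_s half-width of the temporal neighbourhood in seconds.
#' @param amplitude_floor absolute amplitude floor in uV (0 = off).
#' @return Object of class `criteria_config`.
#' @export
criteria_config <- function(ratio_local = 0.05, ratio_max = 0.50,
                            neighborhood_s = 2, amplitude_floor = 0) {
  stopifnot(ratio_local >= 0, ratio_max >= 0, neighborhood_s >= 0,
            amplitude_floor >= 0)
  structure(list(ratio_local = ratio_local, ratio_max = ratio_max,
                 neighborhood_s = neighborhood_s,
                 amplitude_floor = amplitude_floor),
            class = "criteria_config")
}

#' Significant frequencies per second and channel
#'
#' Applies the three criteria of [criteria_config()] to every (window,
#' channel, bin) of the 1-25 Hz grid simultaneously. The temporal
#' neighbourhood of criterion (a) is truncated at epoch edges; criterion (c)
#' uses the margin bins carried by [windowed_spectra()] so 1 and 25 Hz have
#' four neighbours; ties fail (strict inequality).
#'
#' @param spectra an `epoch_spectra` object.
#' @param cfg a [criteria_config()].
#' @return Object of class `peak_set`: logical array
#'   (window x channel x bin) over the 1-25 Hz grid, with `freqs` attribute.
#' @export
significant_frequencies <- function(spectra, cfg = criteria_config()) {
  stopifnot(inherits(spectra, "epoch_spectra"))
  A <- spectra$amplitudes
  freqs <- spectra$freqs
  sel <- which(freqs >= 1 & freqs <= 25)
  if (min(sel) < 3L || max(sel) > length(freqs) - 2L)
    .stopf("spectra lack the 1 Hz margin needed for the neighbour criterion")
  n_win <- dim(A)[1]

  # (a): running max of each bin over windows within +-neighborhood_s
  local_max <- A
  k <- round(cfg$neighborhood_s)
  if (k > 0 && n_win > 1) {
    for (d in setdiff(-k:k, 0L)) {
      src <- seq_len(n_win) + d
      ok <- src >= 1L & src <= n_win
      local_max[ok, , ] <- pmax(local_max[ok, , , drop = FALSE],
                                A[src[ok], , , drop = FALSE])
    }
  }
  crit_a <- A >= cfg$ratio_local * local_max

  # (b): per-window, per-channel max over the 1-25 Hz bins
  win_max <- apply(A[, , sel, drop = FALSE], c(1, 2), max)
  crit_b <- A >= cfg$ratio_max * c(win_max)   # recycles over bins

  # (c): strictly larger than the four spectral neighbours
  nb <- dim(A)[3]
  gt <- function(d) A[, , sel, drop = FALSE] > A[, , sel + d, drop = FALSE]
  crit_c <- gt(-2L) & gt(-1L) & gt(1L) & gt(2L)

  sig <- crit_a[, , sel, drop = FALSE] & crit_b[, , sel, drop = FALSE] & crit_c
  if (cfg$amplitude_floor > 0)
    sig <- sig & (A[, , sel, drop = FALSE] >= cfg$amplitude_floor)
  dimnames(sig) <- list(NULL, dimnames(A)[[2]], freqs[sel])
  structure(sig, freqs = freqs[sel], class = "peak_set")
}

#' Significant frequencies of one channel-second as numeric values
#'
#' @param peaks a `peak_set`.
#' @param window window index (1-based; window w covers second w-1..w+1).
#' @param channel montage label or index.
#' @return Numeric vector of significant frequencies in Hz.
#' @export
peak_frequencies <- function(peaks, window, channel) {
  f <- attr(peaks, "freqs")
  f[peaks[window, channel, ]]
}
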