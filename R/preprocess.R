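# Odd FIR length from the Hamming-window transition-width heuristic
# (transition ~ 3.3 / N cycles/sample).
#' @keywords internal
fir_taps <- function(fs, transition_hz, n_samples = Inf) {
  taps <- ceiling(3.3 * fs / transition_hz)
  if (taps %% 2 == 0) taps <- taps + 1
  if (taps > n_samples) {
    taps <- max(5L, n_samples - (1 - n_samples %% 2))  # largest odd <= n
    warning("FIR length capped at signal length (", taps,
            " taps); transition band will be wider than requested")
  }
  as.integer(taps)
}

# Zero-phase filtering of each row with a symmetric (linear-phase) FIR:
# centred FFT convolution, so group delay is exactly compensated.
#' @keywords internal
apply_fir <- function(data, h) {
  L <- length(h)
  half <- (L - 1L) %/% 2L
  n <- ncol(data)
  out <- data
  for (i in seq_len(nrow(data))) {
    x <- c(data[i, ], numeric(L - 1L))
    full <- signal::fftfilt(h, x)          # causal; delay = half samples
    out[i, ] <- full[(half + 1L):(half + n)]
  }
  out
}

#' Zero-phase FIR band-pass filter
#'
#' Window-design (Hamming) FIR band-pass applied per channel with exact
#' zero-phase response, so downstream instantaneous-phase estimates are not
#' biased by group delay. Filter length follows the transition-width
#' heuristic (default 2 Hz transition).
#'
#' @param rec An `eeg_recording`.
#' @param low_hz,high_hz Band edges in Hz; `0 < low_hz < high_hz < fs/2`.
#' @param transition_hz Transition-band width used to size the FIR
#'   (default 2 Hz).
#' @return A filtered `eeg_recording` of identical shape.
#' @export
bandpass <- function(rec, low_hz, high_hz, transition_hz = 2) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$fs / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq)) {
    stop("band edges must satisfy 0 < low < high < fs/2 = ", nyq, " Hz")
  }
  taps <- fir_taps(rec$fs, transition_hz, ncol(rec$data))
  h <- signal::fir1(taps - 1L, c(low_hz, high_hz) / nyq, type = "pass")
  out <- rec
  out$data <- apply_fir(rec$data, h)
  out
}

#' Zero-phase FIR notch (band-stop) filter
#'
#' Rejects a narrow band around `freq_hz` (default half-width 2 Hz),
#' leaving the passband flat; intended for mains interference.
#'
#' @param rec An `eeg_recording`.
#' @param freq_hz Centre frequency to reject, in (0, fs/2).
#' @param half_width_hz Half-width of the stop band (default 2 Hz).
#' @param transition_hz Transition-band width used to size the FIR
#'   (default 1 Hz).
#' @return A filtered `eeg_recording` of identical shape.
#' @export
notch <- function(rec, freq_hz, half_width_hz = 2, transition_hz = 1) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$fs / 2
  if (!(freq_hz > 0 && freq_hz < nyq)) {
    stop("notch frequency must lie in (0, fs/2) = (0, ", nyq, ") Hz")
  }
  lo <- max(freq_hz - half_width_hz, 1e-6)
  hi <- min(freq_hz + half_width_hz, nyq - 1e-6)
  taps <- fir_taps(rec$fs, transition_hz, ncol(rec$data))
  h <- signal::fir1(taps - 1L, c(lo, hi) / nyq, type = "stop")
  out <- rec
  out$data <- apply_fir(rec$data, h)
  out
}

#' Remove per-channel baseline (DC offset)
#'
#' Subtracts each channel's mean, preventing zero drift from biasing
#' filters and spectra.
#'
#' @param rec An `eeg_recording`.
#' @return An `eeg_recording` whose channels all have zero mean.
#' @export
remove_baseline <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  out <- rec
  out$data <- rec$data - rowMeans(rec$data)
  out
}

#' Extract the 30-50 Hz gamma band
#'
#' Convenience wrapper for [bandpass()] with the fixed gamma-band edges used
#' throughout balance analysis.
#'
#' @param rec An `eeg_recording`.
#' @param ... Passed to [bandpass()].
#' @return A gamma-band `eeg_recording`.
#' @export
gamma_band <- function(rec, ...) bandpass(rec, 30, 50, ...)

#' Standard preprocessing chain
#'
#' Notch (mains), broad band-pass, baseline removal, then gamma-band
#' extraction -- the default path from a raw recording to the signals the
#' phase metrics operate on.
#'
#' @param rec An `eeg_recording`.
#' @param notch_hz Mains frequency (default 50 Hz); `NULL` skips the notch.
#' @param band Broad band-pass edges (default `c(1, 50)` Hz).
#' @param gamma Gamma-band edges (default `c(30, 50)` Hz); `NULL` skips.
#' @return A preprocessed `eeg_recording`.
#' @export
preprocess_recording <- function(rec, notch_hz = 50, band = c(1, 50),
                                 gamma = c(30, 50)) {
  if (!is.null(notch_hz)) rec <- notch(rec, notch_hz)
  rec <- bandpass(rec, band[1], band[2])
  rec <- remove_baseline(rec)
  if (!is.null(gamma)) rec <- bandpass(rec, gamma[1], gamma[2])
  rec
}

#' Segment a recording into non-overlapping sliding windows
#'
#' Cuts the signal into consecutive fixed-length windows (default use:
#' 0.2 s); a trailing partial window is discarded. Start offsets into the
#' parent recording are kept for provenance.
#'
#' @param x An `eeg_recording` or `eeg_analytic` object.
#' @param window_s Window length in seconds; `window_s * fs` must be at
#'   least 2 samples and no longer than the recording.
#' @return An `eeg_windows` object: list with `windows` (list of channels x
#'   window-samples matrices), `window_s`, `source_indices` (1-based start
#'   samples), `fs`, `layout`.
#' @export
segment <- function(x, window_s) UseMethod("segment")

#' @keywords internal
segment_matrix <- function(data, fs, layout, window_s) {
  wsamp <- round(window_s * fs)
  n <- ncol(data)
  if (wsamp < 2) stop("window of ", wsamp, " samples is too short (need >= 2)")
  if (wsamp > n) stop("window (", wsamp, " samples) is longer than the ",
                      "recording (", n, " samples)")
  nwin <- n %/% wsamp
  starts <- (seq_len(nwin) - 1L) * wsamp + 1L
  wins <- lapply(starts, function(s) data[, s:(s + wsamp - 1L), drop = FALSE])
  structure(list(windows = wins, window_s = window_s,
                 source_indices = starts, fs = fs, layout = layout),
            class = "eeg_windows")
}

#' @export
segment.eeg_recording <- function(x, window_s) {
  segment_matrix(x$data, x$fs, x$layout, window_s)
}

#' @export
print.eeg_windows <- function(x, ...) {
  cat(sprintf("<eeg_windows> %d windows of %g s (%d samples) @ %g Hz\n",
              length(x$windows), x$window_s,
              if (length(x$windows)) ncol(x$windows[[1]]) else 0L, x$fs))
  invisible(x)
}
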