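#' Welch power spectral density estimate per channel
#'
#' Splits each channel into L possibly overlapping segments of M samples,
#' tapers each segment, and averages the modified periodograms
#' P_i(w) = |sum_n x_i(n) c(n) exp(-jwn)|^2 / (M U') over segments. The
#' normalization uses U' = fs * sum(c^2) (density scaling folded into the
#' taper-power factor), so a white-noise input of variance s^2 integrates to
#' s^2 over the one-sided band.
#'
#' @param rec An `eeg_recording` (or channels x samples matrix with `fs`).
#' @param segment_len Segment length M in samples (default 1 s of samples).
#' @param overlap_frac Fractional overlap between adjacent segments in
#'   \[0, 1) (default 0.5).
#' @param window_fn Taper: `"hamming"`, `"hanning"` or `"boxcar"`.
#' @param fs Sampling rate, if `rec` is a bare matrix.
#' @return A `psd_estimate`: `freqs` (Hz), `power` (channels x freqs,
#'   units^2/Hz, one-sided), `segment_len`, `n_segments`, `window_fn`,
#'   `overlap_frac`, `norm_factor`, `fs`, `layout`.
#' @export
welch_psd <- function(rec, segment_len = NULL, overlap_frac = 0.5,
                      window_fn = c("hamming", "hanning", "boxcar"),
                      fs = NULL) {
  layout <- NULL
  if (inherits(rec, "eeg_recording")) {
    fs <- rec$fs; layout <- rec$layout; x <- rec$data
  } else {
    x <- if (is.vector(rec)) matrix(rec, nrow = 1) else rec
    if (is.null(fs)) stop("`fs` required for matrix input")
  }
  window_fn <- match.arg(window_fn)
  n <- ncol(x)
  if (is.null(segment_len)) segment_len <- min(round(fs), n)
  M <- as.integer(segment_len)
  if (M > n) stop("segment length (", M, ") exceeds data length (", n, ")")
  if (M < 2) stop("segment length must be at least 2 samples")
  stopifnot(overlap_frac >= 0, overlap_frac < 1)

  taper <- switch(window_fn,
                  hamming = signal::hamming(M),
                  hanning = signal::hanning(M),
                  boxcar = rep(1, M))
  U <- sum(taper^2)
  hop <- max(1L, as.integer(round(M * (1 - overlap_frac))))
  starts <- seq(1L, n - M + 1L, by = hop)
  L <- length(starts)
  nf <- M %/% 2L + 1L
  freqs <- (seq_len(nf) - 1L) * fs / M
  scale1 <- rep(2, nf)
  scale1[1] <- 1
  if (M %% 2 == 0) scale1[nf] <- 1    # Nyquist bin not doubled

  power <- matrix(0, nrow(x), nf, dimnames = list(rownames(x), NULL))
  for (i in seq_len(nrow(x))) {
    acc <- numeric(nf)
    for (s in starts) {
      seg <- x[i, s:(s + M - 1L)] * taper
      X <- stats::fft(seg)[seq_len(nf)]
      acc <- acc + (Mod(X)^2) / (fs * U)
    }
    power[i, ] <- scale1 * acc / L
  }
  structure(list(freqs = freqs, power = power, segment_len = M,
                 n_segments = L, window_fn = window_fn,
                 overlap_frac = overlap_frac, norm_factor = U,
                 fs = fs, layout = layout),
            class = "psd_estimate")
}

#' @export
print.psd_estimate <- function(x, ...) {
  cat(sprintf(
    "<psd_estimate> %d channels, %d freqs (0-%g Hz), %d x %d-sample %s segments\n",
    nrow(x$power), length(x$freqs), max(x$freqs), x$n_segments,
    x$segment_len, x$window_fn))
  invisible(x)
}

#' @keywords internal
band_power_per_channel <- function(psd, band) {
  keep <- psd$freqs >= band[1] & psd$freqs <= band[2]
  if (sum(keep) < 2) {
    stop("band [", band[1], ", ", band[2], "] Hz covers fewer than two ",
         "frequency bins")
  }
  f <- psd$freqs[keep]
  apply(psd$power[, keep, drop = FALSE], 1, function(p) {
    sum((p[-1] + p[-length(p)]) / 2 * diff(f))   # trapezoid
  })
}

#' Per-region mean band power
#'
#' Integrates each channel's PSD over a frequency band (trapezoid rule) and
#' averages the band power over the channels of each scalp region.
#'
#' @param psd A `psd_estimate`.
#' @param layout An `eeg_layout` (defaults to the layout stored in `psd`).
#' @param band Length-2 numeric band in Hz (default the 30-50 Hz gamma
#'   band).
#' @return A data.frame with columns `region`, `band_power` (mean over the
#'   region's channels), `n_channels`.
#' @export
region_psd_summary <- function(psd, layout = NULL, band = c(30, 50)) {
  stopifnot(inherits(psd, "psd_estimate"))
  layout <- layout %||% psd$layout
  if (is.null(layout)) stop("no channel layout available")
  if (band[2] <= band[1]) stop("empty frequency band")
  bp <- band_power_per_channel(psd, band)
  regions <- c("frontal", "central", "occipital")
  out <- data.frame(
    region = regions,
    band_power = vapply(regions, function(r) {
      ch <- region_channels(layout, r)
      mean(bp[match(ch, layout$labels)])
    }, numeric(1)),
    n_channels = vapply(regions, function(r)
      length(region_channels(layout, r)), numeric(1)),
    row.names = NULL)
  out
}
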