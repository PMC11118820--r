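#' Analytic signal via the Hilbert transform
#'
#' Extends each real channel r(t) to its complex analytic signal
#' R(t) = r(t) + j H\[r\](t) = A(t) exp(j phi(t)) using the FFT method
#' (positive frequencies doubled, negative zeroed), giving instantaneous
#' amplitude A(t) and phase phi(t) free of amplitude interference.
#' Constant (including all-zero) channels have no defined phase and are
#' flagged degenerate; metric operations reject them.
#'
#' @param x An `eeg_recording`, a channels x samples numeric matrix, or a
#'   numeric vector (treated as one channel).
#' @param fs Sampling rate in Hz (taken from the recording if given one).
#' @return An `eeg_analytic` object: `analytic` (complex matrix),
#'   `amplitude`, `phase` (radians in (-pi, pi\]), `fs`, `layout` (or NULL),
#'   `degenerate` (logical per channel).
#' @examples
#' t <- seq(0, 1, by = 1 / 250)
#' a <- analytic_signal(cos(2 * pi * 40 * t), fs = 250)
#' range(a$amplitude[1, 26:225])   # ~1 away from the edges
#' @export
analytic_signal <- function(x, fs = NULL) {
  layout <- NULL
  if (inherits(x, "eeg_recording")) {
    fs <- x$fs; layout <- x$layout; x <- x$data
  }
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  stopifnot(is.matrix(x), is.numeric(x), !is.null(fs), fs > 0)
  n <- ncol(x)
  if (n < 2) stop("need at least 2 samples per channel")
  if (!all(is.finite(x))) stop("non-finite values in input")

  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    if (n > 2) h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  z <- matrix(0i, nrow(x), n, dimnames = dimnames(x))
  for (i in seq_len(nrow(x))) {
    z[i, ] <- stats::fft(stats::fft(x[i, ]) * h, inverse = TRUE) / n
  }
  degen <- apply(x, 1, function(r) max(r) - min(r) < 1e-12 * max(1, abs(r[1])))
  structure(list(analytic = z, amplitude = Mod(z), phase = Arg(z),
                 fs = fs, layout = layout, degenerate = degen),
            class = "eeg_analytic")
}

#' @export
print.eeg_analytic <- function(x, ...) {
  cat(sprintf("<eeg_analytic> %d channels x %d samples @ %g Hz%s\n",
              nrow(x$analytic), ncol(x$analytic), x$fs,
              if (any(x$degenerate)) sprintf(" (%d degenerate)",
                                             sum(x$degenerate)) else ""))
  invisible(x)
}

#' @export
segment.eeg_analytic <- function(x, window_s) {
  ws <- segment_matrix(x$analytic, x$fs, x$layout, window_s)
  attr(ws, "analytic") <- TRUE
  attr(ws, "degenerate") <- x$degenerate
  ws
}

#' @keywords internal
chan_index <- function(a, label) {
  labels <- if (!is.null(a$layout)) a$layout$labels else rownames(a$analytic)
  if (is.numeric(label)) {
    if (label < 1 || label > nrow(a$analytic)) stop("channel index out of range")
    return(as.integer(label))
  }
  i <- match(label, labels)
  if (is.na(i)) stop("unknown channel label: ", label)
  i
}

#' @keywords internal
check_not_degenerate <- function(a, idx) {
  if (any(a$degenerate[idx])) {
    labels <- if (!is.null(a$layout)) a$layout$labels else
      as.character(seq_along(a$degenerate))
    stop("phase undefined for degenerate (constant) channel(s): ",
         paste(labels[idx[a$degenerate[idx]]], collapse = ", "))
  }
}

#' Instantaneous phase difference between two channels
#'
#' theta(t) = wrap(phi_s1(t) - phi_s2(t)), wrapped into (-pi, pi].
#'
#' @param a An `eeg_analytic`.
#' @param pair Length-2 vector of channel labels (or indices).
#' @return A `phase_diff` object with `theta` (radians) and `pair`.
#' @export
phase_difference <- function(a, pair) {
  stopifnot(inherits(a, "eeg_analytic"), length(pair) == 2L)
  i <- chan_index(a, pair[1]); j <- chan_index(a, pair[2])
  check_not_degenerate(a, c(i, j))
  structure(list(theta = wrap_pi(a$phase[i, ] - a$phase[j, ]),
                 pair = pair),
            class = "phase_diff")
}

#' @keywords internal
new_pair_metric <- function(value, metric, pair, n, signed = NULL) {
  structure(list(value = value, metric = metric, pair = pair,
                 n_samples = n, signed = signed),
            class = "pair_metric")
}

#' @export
print.pair_metric <- function(x, ...) {
  cat(sprintf("<pair_metric> %s(%s, %s) = %.4f  (N = %d)\n", x$metric,
              x$pair[1], x$pair[2], x$value, x$n_samples))
  invisible(x)
}

#' Phase-locking value (PLV)
#'
#' Modulus of the time-averaged unit phasor of the phase difference:
#' PLV = | (1/N) sum_t exp(j theta(t)) |. PLV = 1 means complete phase
#' locking; PLV = 0 means no consistent phase relation.
#'
#' @param theta A `phase_diff` (or numeric vector of phase differences in
#'   radians, in which case `pair` may name the channels).
#' @param pair Optional channel pair for labelling when `theta` is numeric.
#' @return A `pair_metric` with `metric = "PLV"`, value in \[0, 1\].
#' @export
plv <- function(theta, pair = c("s1", "s2")) {
  if (inherits(theta, "phase_diff")) { pair <- theta$pair; theta <- theta$theta }
  stopifnot(is.numeric(theta), length(theta) >= 2, all(is.finite(theta)))
  v <- Mod(mean(exp(1i * theta)))
  new_pair_metric(min(v, 1), "PLV", pair, length(theta))
}

#' Phase lag index (PLI)
#'
#' Mean sign of the sine of the phase difference,
#' PLI = | (1/N) sum_t sign(sin theta(t)) | (sign(0) = 0). Insensitive to
#' zero-lag (volume-conducted) coupling since symmetric phase differences
#' around 0 or pi cancel. The signed mean is retained in the `signed` field;
#' the reported `value` is its absolute value.
#'
#' @inheritParams plv
#' @return A `pair_metric` with `metric = "PLI"`, value in \[0, 1\].
#' @export
pli <- function(theta, pair = c("s1", "s2")) {
  if (inherits(theta, "phase_diff")) { pair <- theta$pair; theta <- theta$theta }
  stopifnot(is.numeric(theta), length(theta) >= 2, all(is.finite(theta)))
  s <- mean(sign(sin(theta)))
  new_pair_metric(abs(s), "PLI", pair, length(theta), signed = s)
}

#' Weighted phase lag index (wPLI)
#'
#' wPLI = | mean_t Im X(t) | / mean_t | Im X(t) |, where
#' X(t) = R_s1(t) conj(R_s2(t)) is the instantaneous cross-spectrum of the
#' two analytic signals. Each sample's phase lead/lag is weighted by the
#' magnitude of the imaginary cross-spectrum, reducing sensitivity to noise
#' around zero lag. A pure zero-lag relation (Im X identically 0) is
#' defined as wPLI = 0.
#'
#' @param a An `eeg_analytic`.
#' @param pair Length-2 vector of channel labels (or indices).
#' @return A `pair_metric` with `metric = "wPLI"`, value in \[0, 1\].
#' @export
wpli <- function(a, pair) {
  stopifnot(inherits(a, "eeg_analytic"), length(pair) == 2L)
  i <- chan_index(a, pair[1]); j <- chan_index(a, pair[2])
  check_not_degenerate(a, c(i, j))
  imx <- Im(a$analytic[i, ] * Conj(a$analytic[j, ]))
  den <- mean(abs(imx))
  v <- if (den == 0) 0 else abs(mean(imx)) / den
  new_pair_metric(min(v, 1), "wPLI", pair, ncol(a$analytic))
}

#' Pairwise connectivity matrix for one metric
#'
#' Computes the chosen synchronization metric for every distinct channel
#' pair (C(n, 2) values; 171 for the 19-channel montage) and returns a
#' symmetric channels x channels matrix. The diagonal is 1 for PLV and 0
#' for PLI/wPLI. Degenerate channels produce NA rows/columns and a warning
#' rather than silent zeros.
#'
#' @param a An `eeg_analytic` (one window or a full record).
#' @param metric One of `"PLV"`, `"PLI"`, `"wPLI"`.
#' @return An `fc_matrix`: `values` (symmetric matrix with channel
#'   dimnames), `metric`, `layout`, `n_windows_averaged = 1`.
#' @export
pairwise_matrix <- function(a, metric = c("wPLI", "PLV", "PLI")) {
  stopifnot(inherits(a, "eeg_analytic"))
  metric <- match.arg(metric)
  nch <- nrow(a$analytic)
  labels <- if (!is.null(a$layout)) a$layout$labels else
    rownames(a$analytic) %||% as.character(seq_len(nch))
  vals <- matrix(if (metric == "PLV") 1 else 0, nch, nch,
                 dimnames = list(labels, labels))
  Z <- a$analytic
  P <- a$phase
  for (i in seq_len(nch - 1L)) {
    for (j in (i + 1L):nch) {
      if (a$degenerate[i] || a$degenerate[j]) { vals[i, j] <- NA_real_; next }
      v <- switch(metric,
        PLV  = Mod(mean(exp(1i * (P[i, ] - P[j, ])))),
        PLI  = abs(mean(sign(sin(wrap_pi(P[i, ] - P[j, ]))))),
        wPLI = {
          imx <- Im(Z[i, ] * Conj(Z[j, ]))
          den <- mean(abs(imx))
          if (den == 0) 0 else abs(mean(imx)) / den
        })
      vals[i, j] <- min(v, 1)
    }
  }
  vals[lower.tri(vals)] <- t(vals)[lower.tri(vals)]
  if (any(a$degenerate)) {
    warning("degenerate channel(s) flagged NA: ",
            paste(labels[a$degenerate], collapse = ", "))
    diag(vals)[a$degenerate] <- NA_real_
  }
  new_fc_matrix(vals, metric, a$layout, 1L)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
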