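#' @keywords internal
wrap_pi <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

# Best & Fisher (1979) rejection sampler; batch-vectorized.
# kappa ~ 0 degenerates to the uniform circular distribution.
#' @keywords internal
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (n == 0L) return(numeric(0))
  if (kappa < 1e-8) return(wrap_pi(stats::runif(n, -pi, pi) + mu))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0L
  while (i < n) {
    m <- n - i
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    k <- sum(ok)
    if (k > 0L) {
      out[(i + 1L):(i + k)] <- sign(u3[ok] - 0.5) * acos(pmin(pmax(f[ok], -1), 1))
      i <- i + k
    }
  }
  wrap_pi(out + mu)
}

# 1/f^alpha noise via spectral shaping of white Gaussian noise, unit sd.
#' @keywords internal
one_over_f_noise <- function(n, alpha = 1) {
  w <- stats::rnorm(n)
  if (alpha == 0) return(w)
  k <- 0:(n - 1)
  d <- pmin(k, n - k)                # symmetric frequency index
  gain <- ifelse(d == 0, 0, d^(-alpha / 2))
  x <- Re(stats::fft(stats::fft(w) * gain, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Construct a planted coupling event
#'
#' A coupling event is an interval during which the listed channel pairs
#' phase-lock: the second channel of each pair tracks the first at a fixed
#' mean phase lag, with von Mises jitter whose concentration grows with
#' `coupling_strength`. Events emulate the randomly timed moments of active
#' balance adjustment embedded in an otherwise resting recording.
#'
#' @param start_s Onset in seconds (>= 0).
#' @param duration_s Duration in seconds (> 0).
#' @param channel_pairs List of length-2 character vectors of channel labels.
#' @param phase_lag_rad Mean phase lag in radians, in (-pi, pi].
#' @param coupling_strength Dimensionless strength in \[0, 1\]; mapped to the
#'   von Mises concentration kappa = 20 * strength^2.
#' @return An object of class `coupling_event`.
#' @export
coupling_event <- function(start_s, duration_s, channel_pairs,
                           phase_lag_rad = pi / 2, coupling_strength = 1) {
  stopifnot(start_s >= 0, duration_s > 0,
            coupling_strength >= 0, coupling_strength <= 1,
            phase_lag_rad > -pi, phase_lag_rad <= pi)
  if (!is.list(channel_pairs)) channel_pairs <- list(channel_pairs)
  for (p in channel_pairs) {
    if (length(p) != 2L || !is.character(p)) {
      stop("each channel pair must be a length-2 character vector")
    }
  }
  structure(list(start_s = start_s, duration_s = duration_s,
                 channel_pairs = channel_pairs,
                 phase_lag_rad = phase_lag_rad,
                 coupling_strength = coupling_strength),
            class = "coupling_event")
}

#' @keywords internal
kappa_of_strength <- function(s, scale = 20) scale * s^2

#' Generate a synthetic multichannel EEG recording with planted coupling
#'
#' Channels are independent gamma-band phase-diffusion (Wiener-phase)
#' oscillators at a 40 Hz carrier. During a [coupling_event()] the second
#' channel of each listed pair is re-drawn to track the first at the event's
#' mean lag with von Mises jitter (concentration `20 * strength^2`). Signals
#' are then blended with a zero-lag common source at weight `mixing_strength`
#' (an instantaneous linear-mixing stand-in for volume conduction) and 1/f^a
#' background noise is added at a fixed broadband signal-to-noise ratio.
#'
#' @param layout An [channel_layout()] object.
#' @param duration_s Recording length in seconds.
#' @param fs Sampling rate in Hz; must exceed twice the carrier-band upper
#'   edge.
#' @param events List of [coupling_event()] objects (possibly empty).
#' @param noise_exponent Spectral slope a of the 1/f^a background (default 1).
#' @param mixing_strength Weight in \[0, 1\] of the zero-lag common source.
#' @param seed Integer seed; identical arguments and seed give bit-identical
#'   output.
#' @param snr_db Broadband SNR of carrier vs. background noise (default 5 dB).
#' @param carrier_hz Oscillator centre frequency (default 40, mid gamma).
#' @param carrier_band_hz Nominal band of the carriers, used for the Nyquist
#'   check (default c(30, 50)).
#' @param drift_rate Phase-diffusion rate D in rad^2/s (default 10; about a
#'   1.6 Hz Lorentzian linewidth, so uncoupled pairs decorrelate within
#'   ~0.1 s).
#' @param channel_gains Per-channel amplitude gains, recycled to the channel
#'   count (default 1 = unit-RMS carriers).
#' @return A list with components `recording` (class `eeg_recording`: fields
#'   `data` channels x samples in microvolt-like units, `fs`, `layout`) and
#'   `ground_truth` (class `eeg_ground_truth`: `events`, `mixing_matrix`
#'   channels x (channels + 1), `noise_exponent`, `carrier_band_hz`, plus the
#'   calibration constants used).
#' @examples
#' lay <- channel_layout()
#' ev <- coupling_event(1, 2, list(c("Fz", "Cz")), pi / 2, 1)
#' sim <- generate_recording(lay, duration_s = 5, fs = 250, events = list(ev),
#'                           mixing_strength = 0, seed = 1)
#' dim(sim$recording$data)
#' @export
generate_recording <- function(layout, duration_s, fs, events = list(),
                               noise_exponent = 1, mixing_strength = 0,
                               seed = 1L, snr_db = 5, carrier_hz = 40,
                               carrier_band_hz = c(30, 50), drift_rate = 10,
                               channel_gains = 1) {
  stopifnot(inherits(layout, "eeg_layout"), duration_s > 0, fs > 0,
            mixing_strength >= 0, mixing_strength <= 1)
  if (fs < 2 * carrier_band_hz[2]) {
    stop("fs = ", fs, " Hz is below the Nyquist rate of the carrier band (",
         2 * carrier_band_hz[2], " Hz)")
  }
  for (ev in events) {
    stopifnot(inherits(ev, "coupling_event"))
    if (ev$start_s + ev$duration_s > duration_s) {
      stop("coupling event at ", ev$start_s, " s extends past the ",
           duration_s, " s recording")
    }
    for (p in ev$channel_pairs) {
      if (!all(p %in% layout$labels)) {
        stop("event references unknown channel(s): ",
             paste(setdiff(p, layout$labels), collapse = ", "))
      }
    }
  }
  nch <- length(layout$labels)
  n <- round(duration_s * fs)
  gains <- rep_len(channel_gains, nch)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))

  sig_step <- sqrt(drift_rate / fs)      # per-sample phase-diffusion sd
  w0 <- 2 * pi * carrier_hz / fs         # carrier advance per sample

  phi0 <- stats::runif(nch + 1, -pi, pi) # last one: common source
  inc <- matrix(stats::rnorm((nch + 1) * n, mean = w0, sd = sig_step),
                nrow = nch + 1)
  phi <- phi0 + t(apply(inc, 1, cumsum))

  # plant events: slave the second channel of each pair to the first
  ord <- order(vapply(events, `[[`, numeric(1), "start_s"))
  for (ev in events[ord]) {
    i0 <- round(ev$start_s * fs) + 1L
    i1 <- min(round((ev$start_s + ev$duration_s) * fs), n)
    idx <- i0:i1
    kap <- kappa_of_strength(ev$coupling_strength)
    for (p in ev$channel_pairs) {
      a <- match(p[1], layout$labels)
      b <- match(p[2], layout$labels)
      phi[b, idx] <- phi[a, idx] - ev$phase_lag_rad +
        rvonmises(length(idx), 0, kap)
    }
  }

  carriers <- sqrt(2) * cos(phi[seq_len(nch), , drop = FALSE]) * gains
  common <- sqrt(2) * cos(phi[nch + 1, ])

  m <- mixing_strength
  clean <- (1 - m) * carriers + m * matrix(common, nch, n, byrow = TRUE)
  mixing_matrix <- cbind((1 - m) * diag(nch), rep(m, nch))
  rownames(mixing_matrix) <- layout$labels

  noise_scale <- 10^(-snr_db / 20)
  data <- clean
  for (i in seq_len(nch)) {
    rms_i <- sqrt(mean(clean[i, ]^2))
    if (rms_i > 0) {
      data[i, ] <- clean[i, ] +
        noise_scale * rms_i * one_over_f_noise(n, noise_exponent)
    }
  }
  rownames(data) <- layout$labels

  rec <- new_recording(data, fs, layout)
  gt <- structure(list(events = events[ord],
                       mixing_matrix = mixing_matrix,
                       noise_exponent = noise_exponent,
                       carrier_band_hz = carrier_band_hz,
                       carrier_hz = carrier_hz,
                       drift_rate = drift_rate,
                       snr_db = snr_db,
                       kappa_scale = 20,
                       channel_gains = stats::setNames(gains, layout$labels),
                       duration_s = duration_s, fs = fs),
                  class = "eeg_ground_truth")
  list(recording = rec, ground_truth = gt)
}

#' @keywords internal
new_recording <- function(data, fs, layout) {
  stopifnot(is.matrix(data), nrow(data) == length(layout$labels), fs > 0,
            all(is.finite(data)))
  rownames(data) <- layout$labels
  structure(list(data = data, fs = fs, layout = layout),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  invisible(x)
}

#' @export
print.eeg_ground_truth <- function(x, ...) {
  cat(sprintf("<eeg_ground_truth> %d events, mixing weight %.2f, 1/f^%g noise\n",
              length(x$events), 1 - x$mixing_matrix[1, 1], x$noise_exponent))
  invisible(x)
}

# region coupling strengths and amplitude gains per balance paradigm:
# P1 baseline (even); P2 vision blocked (occipital down, frontal/central up);
# P3 proprioception blocked (central down, frontal/occipital up);
# P4 both blocked (frontal carries the load).
#' @keywords internal
paradigm_profile <- function(name) {
  switch(name,
    P1 = list(strength = c(frontal = 0.8,  central = 0.8,  occipital = 0.8),
              gain     = c(frontal = 1.0,  central = 1.0,  occipital = 1.0)),
    P2 = list(strength = c(frontal = 0.9,  central = 0.85, occipital = 0.3),
              gain     = c(frontal = 1.2,  central = 1.1,  occipital = 0.7)),
    P3 = list(strength = c(frontal = 0.9,  central = 0.3,  occipital = 0.85),
              gain     = c(frontal = 1.2,  central = 0.7,  occipital = 1.1)),
    P4 = list(strength = c(frontal = 0.95, central = 0.3,  occipital = 0.3),
              gain     = c(frontal = 1.3,  central = 0.75, occipital = 0.75)),
    stop("unknown paradigm preset: ", name,
         " (expected one of P1, P2, P3, P4)"))
}

#' Synthetic recording preset for one standing-balance paradigm
#'
#' Emulates the four balance conditions obtained by blocking vision and/or
#' proprioception. Balance-adjustment events arrive as a Poisson process;
#' during each event every channel locks onto a shared adjustment rhythm (the
#' frontal core Fz acts as master) with a region-specific coupling strength,
#' and per-event random per-channel phase offsets provide the nonzero lags
#' that phase-lag metrics can detect. Regions additionally get paradigm-
#' specific amplitude gains so spectral power mirrors the planted activation
#' pattern:
#' * P1 -- all regions evenly coupled;
#' * P2 -- vision blocked: frontal/central strong, occipital weak;
#' * P3 -- proprioception blocked: frontal/occipital strong, central weak;
#' * P4 -- both blocked: frontal strong, central and occipital weak.
#'
#' @param name One of `"P1"`, `"P2"`, `"P3"`, `"P4"`.
#' @param seed Integer seed.
#' @param duration_s Recording length (default 180 s, a 3-minute trial).
#' @param fs Sampling rate (default 1000 Hz).
#' @param event_rate_hz Poisson rate of adjustment events (default 0.25/s).
#' @param event_duration_s Event length (default 1 s; together with the rate,
#'   events cover about a quarter of the recording).
#' @param ... Passed on to [generate_recording()] (e.g. `mixing_strength`).
#' @return As [generate_recording()]: `list(recording, ground_truth)`.
#' @export
paradigm_preset <- function(name, seed = 1L, duration_s = 180, fs = 1000,
                            event_rate_hz = 0.25, event_duration_s = 1, ...) {
  prof <- paradigm_profile(name)
  layout <- channel_layout()

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))

  # Poisson event onsets fitting wholly inside the recording
  onsets <- numeric(0)
  t <- stats::rexp(1, event_rate_hz)
  while (t + event_duration_s <= duration_s) {
    onsets <- c(onsets, t)
    t <- t + event_duration_s + stats::rexp(1, event_rate_hz)
  }

  events <- list()
  for (on in onsets) {
    off <- stats::setNames(stats::runif(19, -pi, pi), layout$labels)
    for (cross in list(c("Fz", "Cz"), c("Fz", "Pz"))) {
      reg2 <- layout$region_of[[cross[2]]]
      s <- mean(c(prof$strength[["frontal"]], prof$strength[[reg2]]))
      events[[length(events) + 1L]] <- coupling_event(
        on, event_duration_s, list(cross),
        phase_lag_rad = wrap_pi(off[[cross[1]]] - off[[cross[2]]]),
        coupling_strength = s)
    }
    for (r in c("frontal", "central", "occipital")) {
      core <- core_node(r)
      for (ch in setdiff(region_channels(layout, r), core)) {
        events[[length(events) + 1L]] <- coupling_event(
          on, event_duration_s, list(c(core, ch)),
          phase_lag_rad = wrap_pi(off[[core]] - off[[ch]]),
          coupling_strength = prof$strength[[r]])
      }
    }
  }

  gains <- prof$gain[layout$region_of]
  gen_seed <- (as.integer(seed) * 1009L + match(name, paste0("P", 1:4))) %%
    .Machine$integer.max
  out <- generate_recording(layout, duration_s, fs, events,
                            seed = gen_seed, channel_gains = gains, ...)
  out$ground_truth$paradigm <- name
  out$ground_truth$region_strength <- prof$strength
  out$ground_truth$region_gain <- prof$gain
  out
}
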