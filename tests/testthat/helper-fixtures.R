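# Brute-force oracles: direct elementwise evaluation of the defining
# formulas, independent of the package's vectorized implementations.

brute_plv <- function(theta) {
  acc <- 0 + 0i
  for (t in seq_along(theta)) acc <- acc + exp(1i * theta[t])
  Mod(acc / length(theta))
}

brute_pli <- function(theta) {
  acc <- 0
  for (t in seq_along(theta)) acc <- acc + sign(sin(theta[t]))
  abs(acc / length(theta))
}

brute_wpli <- function(z1, z2) {
  num <- 0; den <- 0
  for (t in seq_along(z1)) {
    ix <- Im(z1[t] * Conj(z2[t]))
    num <- num + ix
    den <- den + abs(ix)
  }
  if (den == 0) 0 else abs(num) / den
}

# single-channel layout for filter tests
one_channel_layout <- function(label = "Fz") {
  channel_layout(label, stats::setNames("frontal", label))
}

# wrap a plain matrix as a recording with a generic layout
matrix_recording <- function(data, fs) {
  labels <- paste0("ch", seq_len(nrow(data)))
  lay <- channel_layout(labels,
                        stats::setNames(rep("frontal", nrow(data)), labels))
  rownames(data) <- labels
  eegfbn:::new_recording(data, fs, lay)
}

# sinusoid recording on the single-channel layout
tone_recording <- function(freq_hz, fs = 1000, duration_s = 10, amp = 1) {
  t <- seq_len(round(duration_s * fs)) / fs
  matrix_recording(matrix(amp * sin(2 * pi * freq_hz * t), 1), fs)
}

# magnitude frequency response of a FIR at one frequency (design oracle)
fir_gain_at <- function(h, freq_hz, fs) {
  k <- seq_along(h) - 1
  Mod(sum(h * exp(-2i * pi * freq_hz * k / fs)))
}

# planted screening scenario: grid-aligned 1 s events on the core pairs,
# ~20% coverage of a 60 s record
planted_screening_sim <- function(seed, fs = 250, strength = 0.9,
                                  lag = pi / 2) {
  set.seed(seed + 1000)
  onsets <- round((seq(1, 56, by = 5) + runif(12, 0, 2)) / 0.2) * 0.2
  events <- lapply(onsets, function(on) {
    coupling_event(on, 1, list(c("Fz", "Cz"), c("Fz", "Pz")), lag, strength)
  })
  generate_recording(channel_layout(), 60, fs, events, seed = seed)
}
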