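---
title: "Phase-synchronization screening and wPLI brain networks: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-synchronization screening and wPLI brain networks: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegfbn)
```

This vignette is the package's account of its methods: the models, the
tunable parameters and their defaults, the numerical choices, and what the
synthetic test bed does and does not establish about real EEG.

## The analysis model

The pipeline targets EEG of *randomly timed* neural events — here,
standing-balance adjustments — embedded in long stretches of resting
signal. It has four stages.

**Preprocessing.** Mains notch (default 50 Hz), broad FIR band-pass
(1–50 Hz), per-channel baseline removal, then extraction of the 30–50 Hz
gamma band, the band most responsive to postural control. All filters are
zero-phase (see *Numerical choices*): phase-sensitive analysis cannot
tolerate group delay.

**Phase extraction.** Each channel $r_i(t)$ is extended to its analytic
signal $R_i(t) = r_i(t) + j\,\mathcal H[r_i](t) = A_i(t) e^{j\varphi_i(t)}$,
so instantaneous phase is defined independently of amplitude. For a channel
pair the phase difference is
$\theta(t) = \varphi_{s_1}(t) - \varphi_{s_2}(t)$ (wrapped to
$(-\pi,\pi]$), and three synchronization metrics are defined on a window of
$N$ samples:

$$\mathrm{PLV} = \Big|\tfrac1N \sum_{t=1}^{N} e^{j\theta(t)}\Big|, \qquad
\mathrm{PLI} = \Big|\tfrac1N \sum_{t=1}^{N} \mathrm{sign}\,
  \Im\big(e^{j\theta(t)}\big)\Big|,$$

$$\mathrm{wPLI} = \frac{\big|\langle \Im X(t)\rangle\big|}
  {\langle |\Im X(t)|\rangle}, \qquad
  X(t) = R_{s_1}(t)\,\overline{R_{s_2}(t)}.$$

PLV responds to any consistent phase relation, including the spurious
zero-lag relations produced by volume conduction. PLI counts only phase
*leads vs. lags* and so ignores zero-lag coupling, but its hard sign
function makes it fragile near $\theta \in \{0, \pi\}$. wPLI weights each
sample by $|\Im X|$, so noisy samples near the real axis — exactly the ones
whose lead/lag sign is unreliable — contribute little.

**Screening.** The gamma-band record is segmented into non-overlapping
0.2 s windows. Each window is scored by the PLV of the core node pairs
Fz–Cz and Fz–Pz (the hubs of the frontal, central and occipital areas),
combined by arithmetic mean; windows scoring in the top fraction
$q = 0.3$ (default) are recombined into the analysis set. Because balance
adjustments are brief and randomly timed, this concentrates the set on the
segments that actually carry coordinated activity.

**Network construction.** On each retained window the wPLI is computed for
all $\binom{19}{2} = 171$ channel pairs; the per-window matrices are
averaged elementwise and the average is binarized into a graph. Node degree
is summarized per region (mean ± SD over the region's channels), and
paradigms are compared by two-sided paired t-tests on per-subject region
degree. Welch PSD per channel, integrated over the gamma band and averaged
per region, provides an energy-based cross-check of the same regional
pattern.

## Tunable parameters

| Parameter | Default | Unit | Rationale |
|---|---|---|---|
| sampling rate `fs` | 1000 | Hz | acquisition-standard rate; all code accepts any `fs` above the carrier band's Nyquist rate |
| band-pass | 1–50 | Hz | standard broad EEG band |
| notch | 50 | Hz | mains frequency |
| gamma band | 30–50 | Hz | band analysed throughout |
| window `window_s` | 0.2 | s | short enough to isolate single adjustments; 200 samples at 1 kHz keeps per-window PLV stable |
| core pairs | Fz–Cz, Fz–Pz | — | region-hub pairings; combination rule `mean` (also `min`, `max`) |
| screening rule | quantile, $q=0.3$ | — | no published threshold exists; a top-fraction rule adapts to the per-recording score distribution, and an absolute-$\tau$ rule is exposed for fixed-criterion use |
| FC metric | wPLI | — | volume-conduction robust; PLV/PLI available |
| edge rule | density $d=0.33$ | — | $\mathrm{round}(0.33 \times 171) = 56$ edges gives a 19-node mean degree near 6, the magnitude typical of reported balance FBNs; absolute-$\tau$ exposed |
| Welch | 1 s segments, 50% overlap, Hamming | — | standard modified-periodogram choices; taper, $M$ and overlap all configurable |

## The synthetic generator

Real recordings for this paradigm are not public, so the generator is a
first-class module whose defaults *are* the study conditions, and every
downstream claim is tested against its planted ground truth.

* **Baseline.** Each channel is an independent phase-diffusion (Wiener
  phase) oscillator: $\varphi_i(t+1) = \varphi_i(t) + \omega_0 +
  \epsilon_t$, carrier 40 Hz, increments of variance $D/f_s$ with
  $D = 10\ \mathrm{rad^2/s}$. This gives a Lorentzian linewidth
  $D/\pi \approx 1.6$ Hz — comfortably inside the gamma band — and an
  analytically predictable decorrelation of uncoupled pairs (below).
* **Coupling events.** During an event the second channel of each listed
  pair is re-drawn as $\varphi_b = \varphi_a - \delta + \eta$, with von
  Mises jitter $\eta$ of concentration $\kappa(s) = 20 s^2$ for coupling
  strength $s \in [0,1]$. $\kappa(1) = 20$ makes the circular resultant
  $\approx 0.975$, so a full-strength event is nearly perfectly locked;
  $\kappa$ monotone in $s$ lets sweeps probe metric sensitivity.
* **Volume conduction.** After coupling, every channel is blended with a
  zero-lag common source: $y_i = (1-m)x_i + m c(t)$. Instantaneous mixing
  is exactly the mechanism that inflates PLV while leaving $\Im X$
  symmetric about zero, so wPLI stays at its noise floor.
* **Noise.** $1/f^{\alpha}$ background ($\alpha = 1$) at 5 dB broadband
  SNR per channel. After gamma-band filtering the in-band SNR is much
  higher (~16 dB), so phase estimates on locked segments remain clean
  while broadband realism is preserved.
* **Presets P1–P4.** Balance-adjustment events arrive as a Poisson process
  (rate 0.25/s, duration 1 s, ≈25% coverage). At each event all 19
  channels lock onto a shared rhythm (Fz as master) with region-specific
  strength, and each channel receives a random per-event phase offset so
  that pair lags are generically nonzero and visible to phase-lag metrics.
  Regional strengths plant the qualitative paradigm patterns (P2:
  frontal/central strong, occipital weak; P3: frontal/occipital strong,
  central weak; P4: frontal dominant). Presets also scale regional carrier
  *amplitude* (e.g. occipital 0.7 in P2): coupling alone cannot move
  spectral power, and the spectral stage is meant to see the same
  activation pattern from the energy side.

**Baseline decorrelation bound.** For two independent phase-diffusion
oscillators the phase difference is a random walk with
$\mathbb E\,e^{j(W_t - W_s)} = e^{-D|t-s|}$, so over a record of length
$T$, $\mathbb E\,[\mathrm{PLV}^2] \approx 2/(T D)$ and $\mathrm{PLV}^2$ is
approximately exponentially distributed. At $T = 60$ s, $D = 10$ this gives
an rms baseline PLV of $\approx 0.058$ and a 99% bound
$\sqrt{-2\ln(0.01)/(TD)} \approx 0.124$. Note that a naive
i.i.d.-samples bound ($3/\sqrt N$ with $N$ the raw sample count) does not
apply: consecutive phase samples are strongly correlated, and the effective
sample count is $\sim T D / 2$, not $T f_s$. The tests assert the 99% bound
per seed and the $< 0.1$ figure for the mean across seeds.

## Numerical choices

* **Zero-phase FIR filtering.** Filters are window-design (Hamming) FIRs
  sized by the transition-width heuristic ($\approx 3.3 f_s/\Delta f$ taps;
  default transitions 2 Hz band-pass, 1 Hz notch), applied as a *centred*
  FFT convolution. For a symmetric (linear-phase) FIR this is exactly
  zero-phase in a single pass. Edges (half the filter length at each end)
  decay toward zero; tests evaluate steady-state behaviour on interior
  samples.
* **Analytic signal on the continuous record.** The Hilbert transform is
  computed by the FFT method on the full filtered record *before*
  segmentation, so 0.2 s windows carry no per-window edge artifacts.
  Per-window computation remains possible (`score_windows` on real-valued
  windows) for pre-segmented input.
* **Degenerate channels.** A constant (or all-zero) channel has no defined
  phase; it is flagged, metric calls on it raise an error, and
  `pairwise_matrix` marks its row/column `NA` with a warning rather than
  writing silent zeros.
* **wPLI 0/0.** A pure zero-lag relation gives $\Im X \equiv 0$; the
  estimator is defined as 0 there (no coupling detectable once zero-lag
  content is discarded).
* **PLI sign convention.** $\mathrm{sign}(0) = 0$; the signed mean is kept
  in the result, the absolute value is reported, so PLI ∈ [0, 1].
* **Selection quantile.** The quantile rule uses R's default (type 7)
  empirical quantile at probability $1-q$, keeping scores at or above it;
  the best window is always kept.
* **Binarization ties.** Under the density rule, equal weights are broken
  by fixed lexicographic channel-pair order, making the graph reproducible
  bit-for-bit.
* **Zero-variance paired tests.** Identical conditions give $t = 0, p = 1$;
  zero-variance nonzero differences are reported as $t = \pm\infty, p = 0$
  rather than an error.
* **Determinism.** Every stochastic entry point takes an integer seed and
  restores the caller's RNG state; identical arguments and seed give
  bit-identical output.

## Validation experiments and problem sizes

The test suite runs the following experiments (sizes chosen to keep each
experiment's sampling error well below the effect it measures):

* *Volume conduction*: 60 s records at 250 Hz, mixing weight 0.5 vs. 0;
  PLV and wPLI averaged over five representative pairs.
* *Metric sensitivity*: `pli_wpli_sweep()` — coupling strengths 0…1 at lag
  $\pi/4$, 2000 samples per strength, additive complex noise (sd 0.4) on
  unit-amplitude signals, 20 seeds; compares the dynamic range of wPLI and
  PLI over the sweep.
* *Screening recovery*: 60 s at 250 Hz, twelve 1 s events (coupling 0.9,
  lag $\pi/2$, ≈20% coverage) on the core pairs, quantile rule $q = 0.2$,
  20 seeds. Event onsets are aligned to the 0.2 s window grid so that the
  ≥50%-overlap truth labels are exact; with unaligned events the number of
  labelled-positive (partially covered) windows structurally exceeds the
  20% selection budget, capping measurable sensitivity at ≈0.83 regardless
  of how well the screener ranks windows. Alignment isolates the quantity
  the experiment is about — ranking quality.
* *Pattern recovery*: presets P2–P4, 60 s at 250 Hz, full pipeline, 20
  seeds per preset; region mean-degree orderings compared with the planted
  ones.
* *Spectral*: Parseval check of the Welch estimator on white noise; peak
  localization on tones; planted P2 regional power contrast.

## What the synthetic bed does not show

The generator emulates phase structure, regional amplitude contrasts, 1/f
background and zero-lag mixing — not real EEG. It has no ocular or muscle
artifacts (the corresponding ICA cleanup step of real pipelines is out of
scope here), no realistic lead fields (mixing is a single global common
source, not a biophysical head model), stationary oscillator statistics
outside events, and sharp event boundaries. Passing tests therefore
establish that the *estimators and the pipeline logic* behave as designed
under known ground truth, not that any particular neurophysiological
conclusion transfers to human recordings. Reported human-data values
(per-pair PLV tables, absolute region degrees) are data-dependent and are
deliberately not targets of the synthetic experiments.

## Known limitations

* EDF input is not implemented; recordings are exchanged as delimited text
  (plus JSON ground-truth sidecars). The reader API keeps a `format`
  argument so a binary reader can slot in.
* The PLI/wPLI estimators average the instantaneous (analytic-signal)
  cross-spectrum within each window; spectrally resolved (tapered,
  Fourier-based) cross-spectra are not provided.
* Only node degree (and weighted strength) are computed on the graph;
  other graph-theoretic indices are out of scope.
* Paired tests are uncorrected for multiple comparisons by default,
  matching common reporting practice for three regions; apply `p.adjust`
  externally when comparing many features.
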