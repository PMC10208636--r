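---
title: "State-resolved oscillatory analysis of hippocampal LFP and spiking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{State-resolved oscillatory analysis of hippocampal LFP and spiking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfposc)
```

## What this package computes

`lfposc` implements an analysis chain for continuous extracellular
recordings from hippocampal CA1 in which theta and gamma rhythms are
*segregated by behavioral state* rather than nested: beta2/slow-gamma
(~20–35 Hz) power dominates active visual search, theta (~3–10 Hz, peak
near 8 Hz) dominates quiescent rest, high frequencies (60–150 Hz) ride
along with theta, and apparent theta-band spike-field coherence can be an
artifact of sharp-wave ripples (SWRs) rather than a sustained oscillation.
The chain has six analysis stages plus a synthetic-session generator that
provides ground truth for every one of them:

1. **Spectral parametrization** — Welch PSD, decomposition into a 1/f^x
   aperiodic component plus Gaussian peaks, the 20–30 Hz sorted spectral
   map, and a per-frequency paired search-vs-rest contrast.
2. **Transient-bout detection** — Morlet wavelet power with joint
   amplitude (chi-square tail above a fitted 1/f background) and duration
   (3 cycles) thresholding, occupancy (`P_episode`) summaries.
3. **Cross-frequency coupling** — power comodulograms with a
   window-shuffling cluster-corrected surrogate test, Hilbert envelope
   correlations, and bicoherence with an AR(1) red-noise null.
4. **SWR detection** — 100–250 Hz events with a rectified, smoothed
   envelope, 3 SD / 50 ms criteria, noise-channel artifact rejection, and
   consolidation with high-gamma (80–120 Hz) and HFO (110–160 Hz) events.
5. **Spike-field coupling** — pairwise phase consistency (PPC) spectra
   with shuffle, Rayleigh, and peak-prominence criteria, and the
   SWR-conditioned decomposition PPC_SWR vs PPC_residual with a
   count-matched reassignment null over six frequency bands.
6. **Spike rhythmicity** — autocorrelogram theta-modulation index from a
   constrained damped-oscillation fit.

## The synthetic-session generator

`synth_config()` / `make_session()` build sessions with the statistical
structure the analyses assume. The generator is first-class, tested code:
its ground-truth tables are what every downstream detector is validated
against.

Defaults (one 10-minute session, rest/search alternating in four blocks):

* **Aperiodic background**: spectrally shaped white noise with exponent
  x = 2 and log10 offset 0 — a typical value for hippocampal LFP over
  1–150 Hz. Shaping is exact by construction (inverse-FFT synthesis), so
  exponent-recovery tests have a perfectly known truth.
* **Bouts**: Hann-tapered narrowband oscillations placed by a per-state
  Poisson process. Theta (8 ± 1 Hz): 6/min in rest, 0.5/min in search,
  mean 1.0 s, amplitude 4 background SD. Beta2 (28 ± 4 Hz): 6/min in
  search, 0.5/min in rest. High frequencies (90 ± 15 Hz): 4/min in rest,
  co-occurring with theta. The literature reports only the *direction* of
  the state dependence; the rates were chosen once to make the rest/search
  asymmetry obvious at session length, and the Hann taper avoids spectral
  splatter at bout edges.
* **SWRs**: a slow biphasic deflection (difference of Gaussians, ~80 ms
  FWHM, energy below 10 Hz, Hann-tapered so the template decays exactly to
  zero) plus a 140 Hz burst. The burst uses a flat-topped Tukey(0.3)
  taper: a configured "(4 SD, 80 ms)" ripple then actually sustains 4 SD
  for ~80 ms, whereas a fully tapered burst would halve its effective
  duration and make the nominal parameters misleading. Ripple amplitude is
  parameterized in SD of the 100–250 Hz filtered background; 6/min in
  rest, 0.2/min in search.
* **Spikes**: inhomogeneous Poisson by thinning with rate
  `base * exp(kappa * cos(theta(t))) / I0(kappa) * gain(t)`. The von Mises
  normalization keeps the time-averaged rate at the base rate; `theta(t)`
  is taken from the noiseless injected oscillation (exact ground truth for
  PPC recovery), and `gain` multiplies the rate inside true SWR windows.
* **Artifacts**: broadband bursts injected on *both* the signal and the
  noise channel, so coincidence rejection is testable.

One global seed fans out to per-component substreams
(`substream_seed`), so a config is bit-reproducible while components stay
independent of each other's randomness consumption.

What the generator deliberately does **not** emulate: biophysical
waveform asymmetries, eye-movement transients, nonstationary behavioral
statistics within a state, electrode drift, or spike-sorting errors.
Passing tests therefore demonstrate that the estimators recover known
structure of this statistical form — not that real recordings satisfy the
generator's assumptions.

## Numerical choices that matter

* **Welch grid**: 1024-sample Hann windows, 50% overlap, and four-fold
  zero-padding to reach a ~0.25 Hz grid at 1 kHz. Zero-padding only
  interpolates the same estimator; Welch statistics are unchanged.
* **Aperiodic/peak fitting**: robust log-log linear fit with candidate
  peak regions (positive residuals beyond 1 SD) excluded, greedy Gaussian
  extraction (tallest residual first, ties toward lower frequency) by
  bounded Levenberg–Marquardt with widths constrained to 0.5–12 Hz, a
  termination cap of 20 peaks, and an aperiodic refit on the
  peak-subtracted spectrum.
* **Wavelets**: 6-cycle Morlet kernels with unit-energy normalization, so
  the mean wavelet power of colored noise tracks the PSD and the log-log
  background fit recovers the generating exponent. Kernels carry 5-sigma
  Gaussian support: harsher truncation leaves sidelobes that sample the
  steep low-frequency end of 1/f^x spectra and bias high-frequency mean
  power by up to ~15%. Samples within one support of the signal edge are
  never detections.
* **Amplitude threshold**: the 95th percentile of a chi-square
  distribution with 2 df (wavelet power of Gaussian noise) scaled to the
  fitted background mean. On pure 1/f^x background the per-frequency
  exceedance sits at 5% ± 1%; note that below ~4 Hz a few hundred seconds
  of signal contain few independent suprathreshold excursions, so
  *per-frequency* occupancy estimates there carry sampling noise and the
  stable statements are band-level.
* **Duration rule**: a detection requires wavelet power above threshold
  for 3 cycles continuously. This crushes background exceedances (band
  occupancy well under 1%), but it cannot reject a brief high-SNR
  transient: the wavelet's own response to an impulse already lasts
  several cycles, so the rule's semantics live in the power domain, not
  the signal domain.
* **SWR envelope**: bandpass, z-score, rectify, then a 1–20 Hz secondary
  bandpass of order 2 — higher orders ring on brief ripple bursts and
  split the envelope bump into sub-50 ms lobes. Envelope z-scoring uses
  median/MAD: mean/SD statistics let the events themselves inflate the
  scale (a few percent duty cycle at 5–7 SD raises the SD by ~25%), making
  the threshold depend on event density; on event-free background the two
  coincide. The 50 ms duration criterion applies to the total time the
  envelope spends above 3 SD within an event (so a one-sample dip does not
  reset the clock), with event edges at the 1 SD crossings; this reading
  yields zero false positives in 20-minute Gaussian nulls while the
  whole-event reading yields ~3/min.
* **Filtering**: all band filters are zero-phase (forward-backward)
  Butterworth with reflective padding sized by the narrowest corner
  period. Very low normalized cutoffs (< ~1e-3) are numerically fragile in
  transfer-function form, so slow envelopes in the generator are
  synthesized directly in the frequency domain instead of filtered.
* **Cluster tests**: cells at p < 0.05 (two-sided against the surrogate
  distribution) are clustered by 4-connectivity, positive and negative
  correlations separately; observed cluster sizes are compared with the
  95th quantile of the surrogate maximum-cluster-size distribution, where
  each surrogate is scored with the same per-cell thresholds.
* **PPC machinery**: phases come from a 5-cycle Hann-windowed complex
  projection (one FFT convolution per frequency; phase 0 = LFP cosine
  peak). Because a 5-cycle window cannot resolve frequencies finer than
  ~f/5, locking appears as a *mesa* in the PPC spectrum; the peak
  criterion therefore marks the whole mesa top (within one prominence of
  the maximum) as on-peak. The SWR-conditioned band test selects the
  band's max-|delta| frequency, so its null is the per-reassignment max
  |delta| over the band — testing the selected frequency against its own
  pointwise null would be anti-conservative, which the uniform-locking
  calibration exposes immediately.
* **Theta-model fit**: the damped-oscillation model is fit with
  Nelder–Mead under box constraints enforced by reparameterization
  (omega in (4, 10) Hz, c in (0, 0.2), tau2 in (0, 0.05) s, tau1 bounded
  to (0.01, 5) s for stability), multi-started over omega in
  {4.5, 6, 7.5, 9} Hz with ties toward lower omega. The oscillatory term
  is cosine-phased: an autocorrelogram is an even function of lag, and a
  sine-phased oscillation is odd — orthogonal to every symmetric curve —
  so under least squares it could never carry weight and every index
  would degenerate to zero. `b` is floored at 1e-3 when forming the index
  `a/b` and fits hitting the floor are flagged; strongly burst-modulated
  units drive `b` toward zero, so their indices are large and
  seed-sensitive (the qualitative statement is index >> 1, against ~0 for
  arrhythmic units).

## Design choices where the field leaves room

* FDR correction is Benjamini–Hochberg throughout.
* The Wilcoxon pairing unit for the state contrast is the session.
* Red noise for the bicoherence null is AR(1) matched to the signal's
  lag-1 autocorrelation and variance.
* Spike-time shuffles redraw times uniformly over the recording (a
  stronger null than local jitter, which would preserve slow rate
  structure).
* Overlapping 600 ms SWR windows are merged before spike partitioning so
  the SWR/residual partition is disjoint and exhaustive; units with fewer
  than 20 SWR-window spikes (or no residual spikes) are excluded with an
  explicit reason.
* "Concurrently detected" on the noise channel means any temporal overlap
  of candidate intervals — the strictest reading, which keeps false SWRs
  out at the cost of losing genuine events that collide with artifacts.

## Known limitations

* The count-matched reassignment null of the SWR-conditioned PPC test
  assumes the two spike populations are exchangeable apart from their
  coupling. Deterministic phase structure that correlates with event
  timing — an infinitely coherent sinusoidal LFP, or strictly periodic
  event windows — violates this and inflates the false-positive rate;
  with finite-coherence oscillations and Poisson event times (the regime
  real recordings live in) the test is calibrated. The validation suite
  uses the realistic regime and the degenerate one is documented here
  rather than asserted against.
* Bicoherence requires stationarity across segments; the AR(1) null
  captures the spectrum's redness but not bout-like nonstationarity.
* The cluster correction uses cluster *size* (cell count). Sizes are
  integers and the threshold comparison is strict, so on coarse grids the
  realized family-wise error sits below the nominal 5% (around 2-3% in the
  shipped calibrations) — the test controls its error rate but is
  conservative, as count-based cluster statistics generally are. A
  mass-based statistic would be continuous and closer to nominal; size is
  the convention this chain follows.
* The bout detector's occupancy is upward-smeared by the wavelet response
  (roughly one wavelet support per bout), which the truth-table
  comparisons budget for explicitly.

## Problem sizes used in validation

The shipped tests exercise the chain end to end on sessions of 30–600 s
at 1 kHz with 100–500 surrogates/shuffles/reassignments per test and up
to 200 repeats for error-rate calibrations; the full-analysis defaults
(5000 permutations, 1000 shuffles) remain the package defaults and are
what `run_pipeline()` uses unless a config block overrides them. The
packaged `demo_config()` runs a complete 10-minute session through every
stage in a few minutes at reduced counts and says so in a message.
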