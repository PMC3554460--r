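---
title: "Detecting and quantifying T-wave alternans with altwave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and quantifying T-wave alternans with altwave}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(altwave)
```

## The problem

T-wave alternans (TWA) is an every-other-beat fluctuation of the T wave's
amplitude or morphology in the surface ECG — a 2:1 oscillation of
ventricular repolarization that is usually far below visual threshold
(tens of microvolts) yet is an established marker of susceptibility to
ventricular arrhythmia and sudden cardiac death. Measuring it requires
detecting a periodic, often non-stationary, microvolt-level signature
buried in millivolt-level ECG.

`altwave` implements a combined algorithm with two stages:

1. **Qualitative detection** in the time–frequency domain. Each T wave's
   total scalogram energy inside the repolarization band is computed from a
   continuous wavelet transform (CWT); the per-beat energies are split into
   odd-beat and even-beat groups, and the Wilcoxon rank-sum test decides
   whether the two groups come from the same distribution. A 2:1 alternans
   makes the groups differ systematically; `p < 0.05` declares TWA.
2. **Quantitative measurement** in the time domain. A template T wave
   (pointwise mean of all T waves) is correlated with each beat:
   the alternans correlation index
   `ACI_i = sum_j(T_ij * Tm_j) / sum_j(Tm_j^2)`
   is 1 for a beat identical to the template and deviates alternately above
   and below 1 under alternans. Runs of at least 7 beats with strictly
   alternating `sign(ACI - 1)` form alternans episodes, and each deviation
   converts to microvolts as
   `ACA_i = 2 |ACI_i - 1| * sum(Tm^2) / sum(|Tm|)`,
   summarized by the mean ACA over episode beats.

The rank-sum stage is distribution-free: it needs no stationarity or phase
assumption about the alternans, which is the practical advantage over
classical spectral estimators on short, non-stationary records.

## The processing chain and its assumptions

`analyze_twa()` runs a fixed order: power-line notch, R-peak detection,
cubic-spline baseline removal, wavelet denoising, a second R-peak pass on
the cleaned signal, RR-stability gate, T-wave extraction, band-limited
energies, rank-sum decision, then (for positive records) quantification.

- **Notch filter.** A second-order IIR notch (Q = 30) at 50 or 60 Hz,
  applied forward–backward for zero phase. The record is padded by periodic
  extension at a whole number of line cycles so the high-Q filter does not
  ring into the record from its edges.
- **R detection.** Detail coefficients of a dyadic à-trous transform with
  the quadratic-spline wavelet behave like smoothed derivatives: the QRS
  produces an opposite-signed modulus-maxima pair whose zero-crossing marks
  the R peak. Pairing happens at scale 2^2, where QRS slopes dominate and
  the much smoother T wave contributes little, with confirmation at scale
  2^3 and an adaptive threshold of 0.3 x the largest modulus maximum within
  +/- 1 s. A 200 ms refractory period keeps the stronger of two conflicting
  candidates.
- **Baseline removal.** One isoelectric knot per beat — inside the TP
  interval when the rhythm is slow enough (window ending `RR - 750` ms
  before R, capped at 250 ms) and in the PR segment (66 ms before R) at
  fast rates — and a natural cubic spline through the knots, held constant
  beyond the first and last beat. The TP-first rule keeps the knots off the
  P wave at normal rates while preserving a usable fallback at high rates.
- **Denoising.** A 4-level *stationary* (undecimated) Daubechies-4 wavelet
  transform with soft universal thresholding of the two finest detail
  levels (content above roughly fs/8). Shift invariance matters here: a
  decimated transform denoises identical beats differently depending on
  their phase against the dyadic grid, which injects a spurious
  beat-parity signal — precisely what the detector looks for. The
  undecimated transform commutes with shifts, so identical beats stay
  identical.
- **Stability gate.** Records with `sd(RR)/mean(RR) >= 0.10` are rejected
  (`status = "rejected_rr"`), not analyzed: a T wave reshaped by sudden
  rate changes mimics alternans. Gating is whole-record; windowed gating
  for long ambulatory records is out of scope.
- **T-wave windows.** The onset follows an empirical rule tied to the
  previous RR interval, `Ts = 40 + 1.33 * sqrt(RR in ms)` ms after the R
  peak (about 82 ms at RR = 1000 ms), with a fixed 400 ms window. A window
  that would cross the next QRS (closer than 40 ms to the next R) or the
  record end drops that beat rather than truncating, so all windows have
  equal length; parity bookkeeping uses the *original* beat number, so a
  dropped beat does not flip the alternation phase of later beats. The
  literal variant `40 + 1.33 * RR` is also available
  (`onset_mode = "literal"`) but puts the onset beyond the beat at normal
  rates; the square-root form is the default because only it lands the
  onset at the ST segment where a 400 ms window actually delimits a T wave.
  Because T-wave energy concentrates in the middle of the wave, the
  decision is robust to moderate RT-interval shifts; the test suite
  includes this property on synthetic data.

## The scalogram energy

The CWT uses a complex Morlet wavelet with centre angular frequency
2*pi, so scale `a` (in samples) maps exactly to `fs / a` Hz. Energies are
summed over a 32-point logarithmic frequency grid spanning 0.5–10 Hz — the
T wave's band — across the 400 ms window, as a plain unweighted sum of
`|T(a,b)|^2` over the grid. No scale weighting (`da/a^2` measure) is
applied: the quantity is only ever *compared between beats*, so any fixed
positive weighting yields the same ranks; the unweighted sum is fixed for
comparability.

Numerical choices:

- Windows are transformed after anti-aliased decimation to 125 Hz
  (zero-phase FIR, cutoff 50 Hz). The band of interest ends at 10 Hz, so a
  62.5 Hz Nyquist retains it with ample margin; every beat passes through
  the identical operator, so exactly equal beats keep exactly equal
  energies, and the 250-record evaluation grid stays at desk-scale runtime.
  `cwt()` itself never resamples; decimation is an `energy_series()`
  parameter (`analysis_fs = NULL` disables it).
- Each window is extended by mirror tiling with half the largest wavelet
  support on both sides and the FFT length is chosen so circular
  convolution equals linear convolution. The identical padding for every
  beat makes residual edge bias cancel between beats.
- Exactly tied pooled energies (a strictly periodic, noise-free record)
  yield the conventional `p = 1`: a rank test is undefined under total
  ties, and the correct call for identical T waves is "no alternans".
- The rank-sum test is exact for combined samples up to 30 without ties
  and uses the tie-corrected normal approximation otherwise.
- Pooled energies closer than 1e-9 (relative) are ranked as tied before
  testing. Floating-point convolution is not bit-reproducible across window
  positions, and its rounding pattern can correlate with beat parity; the
  tie floor keeps the test blind to differences far below any physical
  signal while leaving continuous data untouched.

## Quantification conventions

- The template is the pointwise **mean** (a pointwise median is available
  via `template_stat = "median"` for robustness experiments).
- `ACA_i` uses `|ACI_i - 1|` and `sum(|Tm_j|)` in the denominator so the
  result is a nonnegative amplitude in microvolts.
- The mean ACA averages over beats inside detected episodes when episodes
  exist and over all analyzed beats otherwise (`aca_over = "all"` forces
  the latter). On a record with sustained alternans the two agree closely;
  on fragmented alternans the episode mean is the more faithful summary.
- Quantification runs only on detection-positive records by default
  (`quantify = "auto"`); `"always"` overrides for research use.

For a Gaussian alternans waveform `a` of standard deviation `s_a` added to
a roughly Gaussian T wave of standard deviation `s_T` and matching peak
position, the measured amplitude has a closed-form expectation: the
template is `Tm = T + (k/2) a`, both parities deviate from it by
`(k/2) a`, and

`mean ACA = k * sum(a * Tm) / sum(|Tm|) ~= k * s_a / sqrt(s_a^2 + s_T^2)`.

With the simulator defaults (`s_a` = 40 ms, `s_T` = 28–38 ms across the
five templates) this recovery factor is about 0.72–0.82, i.e. the
quantifier reports roughly three quarters of the injected level — a
structural property of projecting a narrower perturbation onto the whole
T wave, not an estimation error that averaging more beats would remove.
The acceptance script computes the realized values; the test suite checks
that the factor is constant in `k` (linearity) to within 2% on noise-free
records.

## What the simulator emulates — and what it does not

`simulate_twa_record()` and `build_grid()` construct the study conditions:

- **Clean ECG:** periodic repetition of a single 1 s beat at 500 Hz
  (5 uV/LSB on write), so all T waves are identical and the clean signal
  provably contains no alternans. Five synthetic beat templates (sums of
  Gaussian bumps for P, Q, R, S, T with R amplitudes 0.85–1.2 mV, T
  amplitudes 240–380 uV, T widths 28–38 ms) stand in for real
  single-subject beats; a real beat can be supplied as a CSV via
  `make_clean_ecg()`.
- **Alternans:** a unit-peak Gaussian (sd 40 ms, centred on the T peak) or
  the first half-lobe of a Gaussian derivative, scaled by
  `k in {10, 20, 50, 100, 200}` uV and added to every second beat — so the
  beat-to-beat difference of T-wave amplitude equals `k` for the Gaussian
  kind. The half-lobe reading of the derivative shape is one of two
  plausible constructions; it is a package choice, not an asserted fact.
- **Noise:** four surrogate classes, each unit-RMS — white Gaussian;
  baseline wander as three sinusoids in 0.05–0.45 Hz with random phases;
  muscle activity as 20–100 Hz band-passed noise with 1–2 s
  amplitude-modulated bursts; electrode motion as sparse random-sign
  impulses through a 3 Hz first-order low-pass — summed with equal power
  and scaled by `l` so that `10*log10(P_signal / P_(l*noise))` hits the
  target SNR (20–40 dB) over the whole record.
- The full factorial grid is 5 templates x 2 waveforms x 5 levels x
  5 SNRs = 250 alternans-positive records with deterministic per-cell
  seeds, 128 beats per segment by default.

**Caveats.** The surrogates are deliberately simple spectral caricatures.
Real noise-stress-test recordings carry substantially more energy *inside*
the 0.5–10 Hz detection band (real baseline wander is not band-limited to
0.45 Hz, surface EMG extends below 20 Hz, and electrode motion produces
large in-band steps). Detection on this synthetic grid is therefore
*easier* than on recorded noise at the same nominal SNR, and measured
sensitivities here sit at the optimistic end of what the same detector
achieves on real data; the false-positive rate on alternans-free noisy
records remains at the nominal test level (checked in the suite), so the
optimism reflects the noise model, not a biased detector. The simulator
also fixes the rhythm (no heart-rate variability, no ectopy, no
respiration), so passing tests say nothing about alternans phase resets or
rate-dependent repolarization changes.

## Problem sizes and determinism

Tests and the acceptance script run the grid at 128 beats per segment
(about 2 minutes per parity group at 60 bpm), 250 records, with all seeds
fixed or derived deterministically from one base seed; generator seeds
always restore the caller's RNG state. The per-record analysis is
deterministic given the record.

## Known limitations

- Single-lead only; no ectopic-beat handling (ectopy resets alternans
  phase in real data and would need beat classification).
- Whole-record stability gating; ambulatory use would need windowing.
- The spectral-method comparator is a minimal textbook implementation
  (per-sample across-beat periodograms, alternans bin at 0.5 cycles/beat,
  noise reference band 0.33–0.48 cycles/beat) intended as a baseline for
  paired comparisons, not as a validated clinical implementation.
- Episode delineation formalizes "alternating ACI" as strict alternation
  of `sign(ACI - 1)` with 1 breaking a run; other readings (e.g. tolerance
  bands around 1) are plausible and exposed via `tol` in
  `find_episodes()`.
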