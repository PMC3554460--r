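# altwave

Detection and quantification of **T-wave alternans (TWA)** in single-lead
ECG. TWA is a beat-to-beat (2:1) fluctuation of T-wave amplitude or
morphology — typically tens of microvolts, invisible to the eye — and an
established noninvasive risk marker for ventricular arrhythmia and sudden
cardiac death. `altwave` is aimed at biomedical-signal researchers who need
a reproducible TWA pipeline and a controlled synthetic benchmark for it.

## The method

The package implements a combined time–frequency / correlation algorithm:

**Detection.** After preprocessing (power-line notch, cubic-spline baseline
removal, stationary-wavelet denoising, R-peak detection by wavelet
modulus-maxima pairs, and an RR-stability gate `sd(RR)/mean(RR) < 0.10`),
each beat's T wave is delimited by a 400 ms window starting
`Ts = 40 + 1.33 * sqrt(RR)` ms after the R peak. The total scalogram energy

    E = sum over scale a, time b of |T(a, b)|^2 ,
    T(a, b) = a^(-1/2) * sum_t x(t) * conj(psi((t - b) / a))

(complex Morlet psi, 0.5–10 Hz × 400 ms region) gives one energy per beat.
Under 2:1 alternans the odd-beat and even-beat energies form two
systematically different samples; the Wilcoxon rank-sum test on the two
groups declares TWA when `p < 0.05`.

**Quantification.** The template T wave `Tm = (1/N) * sum_i T_i` is
correlated with each beat:

    ACI_i = sum_j(T_ij * Tm_j) / sum_j(Tm_j^2)
    ACA_i = 2 * |ACI_i - 1| * sum_j(Tm_j^2) / sum_j(|Tm_j|)   [uV]

Runs of >= 7 beats with strictly alternating `sign(ACI - 1)` are alternans
episodes; the mean ACA over episode beats is the record's alternans
amplitude. A classical spectral-method estimator (across-beat periodogram,
alternans bin at 0.5 cycles/beat) is included as a comparator, and an
evaluation harness scores sensitivity `Se = TP / (TP + FN) * 100` and
relative amplitude error `RE = |A_true - A_measured| / A_true * 100`
against simulation ground truth.

A synthetic ECG generator provides the benchmark: periodic repetition of a
beat template (so the clean signal provably has no alternans), Gaussian or
Gaussian-derivative alternans waveforms at 10–200 uV added to every second
beat, and four surrogate noise classes (white, baseline wander, muscle,
electrode motion) mixed at equal power and scaled to a 20–40 dB SNR.

## A worked example

Simulate two minutes of ECG with 100 uV alternans at 30 dB SNR, then run
the full pipeline:

```r
library(altwave)

sim <- simulate_twa_record(template = 1, n_beats = 128, k = 100,
                           snr_db = 30, seed = 7)
sim
#> <simulated_record> 128 beats @ 500 Hz, k = 100 uV (gaussian), SNR = 30 dB

res <- analyze_twa(sim$record)
res
#> <twa_analysis> status: twa
#> <twa_detection> TWA detected (p = 1.713e-22, alpha = 0.05; 64 odd vs 64 even beats)
#> <alternans_profile> 128 beats, 1 episode(s), mean ACA 74.98 uV

glance(res)
#> # A tibble: 1 × 6
#>   status  p_value twa_present mean_aca n_beats rr_ratio
#>   <chr>     <dbl> <lgl>          <dbl>   <int>    <dbl>
#> 1 twa    1.71e-22 TRUE            75.0     128        0
```

Reading the output: the rank-sum test separates odd from even T-wave
energies at `p ~ 1.7e-22`, so the record is classified as containing TWA;
quantification finds one sustained episode spanning all 128 beats and a
mean alternans amplitude of about 75 uV. The measured amplitude is
deliberately the projection of the injected waveform onto the whole T
wave, so it recovers roughly three quarters of the injected 100 uV — a
structural property of the correlation estimator, constant across
alternans levels (see the methods vignette).

Per-beat results are tibbles: `tidy(res$detection)` gives the energy
series by parity, `tidy(res$profile)` the per-beat ACI/ACA, and
`autoplot()` works on records, detections, and profiles. A thin CLI with
`simulate / detect / quantify / pipeline / evaluate / reproduce`
subcommands lives at `inst/cli/altwave.R` (exit codes: 0 ran, 2 input
error, 3 rejected by the stability gate).

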