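#' Synthetic beat templates
#'
#' One-second beat templates built as sums of Gaussian bumps (P, Q, R, S, T)
#' at 500 Hz, with five parameter sets spanning common adult morphologies
#' (R amplitude 0.8-1.2 mV, T amplitude 220-380 uV, T width 28-38 ms sd,
#' T peak 250-300 ms after R). The R peak sits at 300 ms so a full T wave
#' fits between successive QRS complexes at 60 bpm. A real single beat can
#' be supplied instead of these via [make_clean_ecg()].
#'
#' @param fs Sampling rate in Hz.
#' @return A list of 5 numeric vectors (uV), each of length `fs`, with
#'   attributes `r_sample` (R-peak index) and `t_peak_sample`.
#' @export
default_beat_templates <- function(fs = 500) {
  # centre_ms, sd_ms, amp_uv for P, Q, R, S, T per template
  par <- list(
    t1 = list(p = c(160, 24, 110), q = c(282, 7, -110), r = c(300, 11, 1000),
      s = c(318, 8, -180), t = c(585, 34, 300)),
    t2 = list(p = c(150, 22, 90), q = c(284, 6, -80), r = c(300, 10, 850),
      s = c(316, 8, -140), t = c(560, 28, 240)),
    t3 = list(p = c(165, 26, 130), q = c(281, 7, -130), r = c(300, 12, 1200),
      s = c(320, 9, -220), t = c(600, 38, 380)),
    t4 = list(p = c(155, 23, 100), q = c(283, 6, -90), r = c(300, 11, 950),
      s = c(317, 8, -160), t = c(575, 31, 270)),
    t5 = list(p = c(162, 25, 120), q = c(282, 7, -120), r = c(300, 10, 1100),
      s = c(319, 9, -200), t = c(590, 36, 330))
  )
  t_ms <- (seq_len(fs) - 1) / fs * 1000
  lapply(par, function(waves) {
    uv <- numeric(length(t_ms))
    for (wv in waves) {
      uv <- uv + wv[3] * exp(-((t_ms - wv[1])^2) / (2 * wv[2]^2))
    }
    structure(uv,
      r_sample = which.max(uv),
      t_peak_sample = round(waves$t[1] / 1000 * fs) + 1L
    )
  })
}

#' Clean periodic ECG from a single beat
#'
#' Periodic repetition of one beat, which guarantees that all T waves are
#' identical so the clean signal contains no alternans by construction.
#'
#' @param beat_template Numeric vector of one beat (uV) whose length equals
#'   the number of samples in one beat period; attributes `r_sample` and
#'   `t_peak_sample` mark the fiducials (defaults: argmax, and 285 ms after
#'   it).
#' @param n_beats Number of repetitions (>= 2).
#' @param fs Sampling rate in Hz.
#' @param label Record label.
#' @return A `simulated_record`: list with `record` (an [ecg_record()]) and
#'   `truth` (true R-peak samples, beat period, fiducials, and an empty
#'   alternans description).
#' @export
make_clean_ecg <- function(beat_template, n_beats = 128, fs = 500,
                           label = "synthetic") {
  if (!length(beat_template)) stop("empty beat template", call. = FALSE)
  if (n_beats < 2) stop("need at least 2 beats", call. = FALSE)
  beat <- as.numeric(beat_template)
  len <- length(beat)
  r_off <- attr(beat_template, "r_sample") %||% which.max(beat)
  t_off <- attr(beat_template, "t_peak_sample") %||% (r_off + round(0.285 * fs))
  uv <- rep(beat, n_beats)
  truth <- list(
    fs = fs,
    beat_len = len,
    n_beats = n_beats,
    r_samples = r_off + (seq_len(n_beats) - 1L) * len,
    t_peak_offset = t_off - r_off,
    alternans = list(k = 0, kind = "none", parity = NA_integer_),
    snr_db = Inf
  )
  structure(
    list(
      record = ecg_record(uv, fs = fs, resolution = 5, label = label),
      truth = truth
    ),
    class = "simulated_record"
  )
}

#' Alternans perturbation waveforms
#'
#' Unit-peak waveforms on a 400 ms support, added to alternate T waves:
#' a Gaussian bump (morphology/amplitude alternation), or the first
#' half-lobe of the Gaussian first derivative (a skewed, partly biphasic
#' shape alternation).
#'
#' @param kind `"gaussian"` or `"gaussian_derivative"`.
#' @param width_ms Gaussian standard deviation in ms.
#' @param fs Sampling rate in Hz.
#' @param duration_ms Support length in ms (default 400).
#' @return Numeric vector of `duration_ms * fs / 1000` samples with
#'   `max(abs(.)) == 1` and attribute `peak_sample` (index of the absolute
#'   peak, used for alignment with the T peak).
#' @export
make_alternans_waveform <- function(kind = c("gaussian", "gaussian_derivative"),
                                    width_ms = 40, fs = 500,
                                    duration_ms = 400) {
  kind <- match.arg(kind)
  if (width_ms <= 0 || width_ms >= duration_ms) {
    stop("`width_ms` must be in (0, duration_ms)", call. = FALSE)
  }
  m <- round(duration_ms / 1000 * fs)
  t_ms <- (seq_len(m) - 1) / fs * 1000 - duration_ms / 2
  if (kind == "gaussian") {
    w <- exp(-t_ms^2 / (2 * width_ms^2))
  } else {
    w <- -t_ms * exp(-t_ms^2 / (2 * width_ms^2))
    w[t_ms > 0] <- 0 # first half-lobe only
  }
  w <- w / max(abs(w))
  structure(w, peak_sample = which.max(abs(w)), kind = kind)
}

#' Inject 2:1 alternans into a clean simulated record
#'
#' Adds `k * waveform` inside the T-wave region of every second beat, the
#' waveform peak aligned with the template's T peak, so the beat-to-beat
#' difference between T-wave maxima equals `k` (for the Gaussian kind).
#'
#' @param sim A `simulated_record` from [make_clean_ecg()].
#' @param waveform From [make_alternans_waveform()].
#' @param k Alternans level in uV (peak amplitude added to alternate beats).
#' @return The perturbed `simulated_record` with updated truth (`k`, `kind`,
#'   and the parity of the modified beats).
#' @export
add_alternans <- function(sim, waveform, k) {
  stopifnot(inherits(sim, "simulated_record"), k >= 0)
  tr <- sim$truth
  uv <- sim$record$uv
  peak_at <- attr(waveform, "peak_sample") %||% which.max(abs(waveform))
  wlen <- length(waveform)
  modified <- integer(0)
  for (b in seq(2L, tr$n_beats, by = 2L)) {
    t_peak <- tr$r_samples[b] + tr$t_peak_offset
    start <- t_peak - peak_at + 1L
    stop_ <- start + wlen - 1L
    if (start < 1L || stop_ > length(uv)) next
    uv[start:stop_] <- uv[start:stop_] + k * waveform
    modified <- c(modified, b)
  }
  tr$alternans <- list(
    k = k,
    kind = attr(waveform, "kind") %||% "custom",
    parity = 0L, # even beats modified
    modified_beats = modified
  )
  structure(
    list(record = ecg_with_samples(sim$record, uv), truth = tr),
    class = "simulated_record"
  )
}

#' Surrogate ECG noise generators
#'
#' Reproducible surrogates for the four contaminant classes, each normalized
#' to unit RMS: `white` Gaussian noise; `baseline_wander` as a sum of three
#' sinusoids with random frequencies in 0.05-0.45 Hz and random phases;
#' `muscle` as 20-100 Hz band-passed noise with slow (about 1-2 s)
#' amplitude-modulated bursts; `electrode_motion` as sparse random-sign
#' impulses smoothed by a first-order low-pass (3 Hz corner). These are
#' synthetic stand-ins for recorded noise-stress-test signals.
#'
#' @param kind One of `"white"`, `"baseline_wander"`, `"muscle"`,
#'   `"electrode_motion"`.
#' @param n Number of samples.
#' @param fs Sampling rate in Hz.
#' @param seed Optional RNG seed (restores the caller's RNG state).
#' @return Numeric vector of length `n` with RMS 1.
#' @export
make_noise <- function(kind = c("white", "baseline_wander", "muscle",
                         "electrode_motion"),
                       n, fs = 500, seed = NULL) {
  kind <- match.arg(kind)
  x <- with_seed(seed, switch(kind,
    white = stats::rnorm(n),
    baseline_wander = {
      f <- stats::runif(3, 0.05, 0.45)
      ph <- stats::runif(3, 0, 2 * pi)
      amp <- stats::runif(3, 0.5, 1)
      tt <- (seq_len(n) - 1) / fs
      colSums(amp * t(sapply(seq_len(3), function(i) sin(2 * pi * f[i] * tt + ph[i]))))
    },
    muscle = {
      raw <- stats::rnorm(n)
      bp <- signal::butter(4, c(20, 100) / (fs / 2), type = "pass")
      burst <- signal::butter(2, 0.7 / (fs / 2), type = "low")
      env <- abs(signal::filtfilt(burst, stats::rnorm(n)))
      env <- 0.2 + env / max(env)
      signal::filtfilt(bp, raw) * env
    },
    electrode_motion = {
      imp <- numeric(n)
      n_imp <- max(2L, stats::rpois(1, lambda = 0.2 * n / fs))
      at <- sample.int(n, n_imp)
      imp[at] <- sample(c(-1, 1), n_imp, replace = TRUE) *
        (0.5 + stats::rexp(n_imp))
      a <- exp(-2 * pi * 3 / fs) # 3 Hz first-order low-pass
      stats::filter(imp * (1 - a), filter = a, method = "recursive")
    }
  ))
  x <- as.numeric(x)
  rms <- sqrt(mean(x^2))
  if (rms == 0) stop("degenerate noise realization", call. = FALSE)
  x / rms
}

#' Equal-power mixture of the four noise classes
#'
#' @inheritParams make_noise
#' @param weights Nonnegative power weights over the classes
#'   (white, baseline_wander, muscle, electrode_motion); default equal.
#' @return Numeric vector of length `n` (approximately unit RMS).
#' @export
mixed_noise <- function(n, fs = 500, seed = NULL,
                        weights = c(1, 1, 1, 1) / 4) {
  stopifnot(length(weights) == 4L, all(weights >= 0), sum(weights) > 0)
  weights <- weights / sum(weights)
  kinds <- c("white", "baseline_wander", "muscle", "electrode_motion")
  out <- numeric(n)
  for (i in seq_along(kinds)) {
    if (weights[i] == 0) next
    s <- if (is.null(seed)) NULL else derive_seed(seed, i)
    out <- out + sqrt(weights[i]) * make_noise(kinds[i], n, fs, seed = s)
  }
  out
}

#' Mix noise into a simulated record at a target SNR
#'
#' Chooses the noise factor `l` so that
#' `10 * log10(P_signal / P_(l * noise)) = snr_db`, powers taken over the
#' whole record after mean removal. The achieved SNR is stored in the truth.
#'
#' @param sim A `simulated_record`.
#' @param noise Numeric noise vector of the same length as the record.
#' @param snr_db Target signal-to-noise ratio in dB; `NULL` leaves the
#'   record unchanged.
#' @return The noised `simulated_record`.
#' @export
mix_to_snr <- function(sim, noise, snr_db) {
  stopifnot(inherits(sim, "simulated_record"))
  if (is.null(snr_db)) {
    return(sim)
  }
  uv <- sim$record$uv
  if (length(noise) != length(uv)) {
    stop("noise and record lengths differ", call. = FALSE)
  }
  p_n <- signal_power(noise)
  if (p_n == 0) stop("zero-power noise with finite target SNR", call. = FALSE)
  p_s <- signal_power(uv)
  l <- sqrt(p_s / (p_n * 10^(snr_db / 10)))
  out <- uv + l * noise
  tr <- sim$truth
  tr$snr_db <- 10 * log10(p_s / signal_power(l * noise))
  tr$noise_factor <- l
  structure(
    list(record = ecg_with_samples(sim$record, out), truth = tr),
    class = "simulated_record"
  )
}

#' One-call TWA record simulator
#'
#' Convenience wrapper: clean periodic ECG from a template, 2:1 alternans at
#' level `k`, and an equal-power four-class noise mixture scaled to the
#' target SNR.
#'
#' @param template A beat template vector, or an index 1-5 into
#'   [default_beat_templates()].
#' @param n_beats Beats per record.
#' @param waveform_kind Passed to [make_alternans_waveform()].
#' @param k Alternans level in uV.
#' @param snr_db Target SNR in dB, or `NULL` for no noise.
#' @param seed RNG seed for the noise.
#' @param fs Sampling rate in Hz.
#' @return A `simulated_record`.
#' @export
simulate_twa_record <- function(template = 1, n_beats = 128,
                                waveform_kind = "gaussian", k = 100,
                                snr_db = 30, seed = NULL, fs = 500) {
  if (is.numeric(template) && length(template) == 1L) {
    template <- default_beat_templates(fs)[[template]]
  }
  sim <- make_clean_ecg(template, n_beats = n_beats, fs = fs)
  if (k > 0) {
    wf <- make_alternans_waveform(waveform_kind, fs = fs)
    sim <- add_alternans(sim, wf, k)
  }
  if (!is.null(snr_db)) {
    noise <- mixed_noise(nrow(sim$record), fs = fs, seed = seed)
    sim <- mix_to_snr(sim, noise, snr_db)
  }
  sim
}

#' The factorial simulation grid
#'
#' Full factorial design used by the evaluation harness: 5 beat templates x
#' 2 alternans waveforms x 5 alternans levels (10, 20, 50, 100, 200 uV) x
#' 5 SNR levels (20, 25, 30, 35, 40 dB) = 250 alternans-positive records,
#' with a deterministic per-cell noise seed derived from `seed`.
#'
#' @param n_templates Number of templates (the shipped set has 5).
#' @param n_beats Beats per record.
#' @param seed Base seed; per-cell seeds are derived deterministically.
#' @param k_levels,snr_levels Factor levels.
#' @return A tibble with one row per cell: `cell`, `template_id`, `waveform`,
#'   `k`, `snr_db`, `n_beats`, `seed`. Realize any row with
#'   [realize_grid_cell()].
#' @export
build_grid <- function(n_templates = 5, n_beats = 128, seed = 1,
                       k_levels = c(10, 20, 50, 100, 200),
                       snr_levels = c(20, 25, 30, 35, 40)) {
  if (n_templates != 5) {
    stop("the factorial design uses exactly 5 beat templates", call. = FALSE)
  }
  grid <- tidyr::expand_grid(
    template_id = seq_len(n_templates),
    waveform = c("gaussian", "gaussian_derivative"),
    k = k_levels,
    snr_db = snr_levels
  )
  grid <- dplyr::mutate(grid,
    cell = dplyr::row_number(),
    n_beats = n_beats,
    seed = vapply(cell, function(i) derive_seed(seed, i), integer(1))
  )
  dplyr::relocate(grid, cell)
}

#' @rdname build_grid
#' @param grid_row One row of the grid tibble.
#' @param fs Sampling rate in Hz.
#' @export
realize_grid_cell <- function(grid_row, fs = 500) {
  stopifnot(nrow(grid_row) == 1L)
  simulate_twa_record(
    template = grid_row$template_id,
    n_beats = grid_row$n_beats,
    waveform_kind = grid_row$waveform,
    k = grid_row$k,
    snr_db = grid_row$snr_db,
    seed = grid_row$seed,
    fs = fs
  )
}

#' @export
print.simulated_record <- function(x, ...) {
  cat(sprintf(
    "<simulated_record> %d beats @ %g Hz, k = %g uV (%s), SNR = %s dB\n",
    x$truth$n_beats, x$truth$fs, x$truth$alternans$k, x$truth$alternans$kind,
    format(x$truth$snr_db, digits = 4)
  ))
  invisible(x)
}
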