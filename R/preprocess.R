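#' Remove power-line interference with a narrow notch filter
#'
#' Second-order IIR notch at the mains frequency (50 or 60 Hz), applied
#' forward-backward for zero phase. Power-line pickup is narrow-band
#' (bandwidth under 1 Hz), so a high-Q notch removes it with negligible
#' passband distortion below 40 Hz.
#'
#' @param record An [ecg_record()].
#' @param line_freq Mains frequency in Hz, 50 or 60.
#' @param q Notch quality factor (centre frequency / -3 dB bandwidth).
#' @return A filtered [ecg_record()] of the same length and sampling rate.
#' @export
notch_filter <- function(record, line_freq = 50, q = 30) {
  stopifnot(is_ecg_record(record))
  fs <- ecg_fs(record)
  if (!line_freq %in% c(50, 60)) {
    stop("`line_freq` must be 50 or 60 Hz", call. = FALSE)
  }
  if (fs <= 2 * line_freq) {
    stop(sprintf(
      "sampling rate %g Hz too low to notch %g Hz (need fs > 2*line_freq)",
      fs, line_freq
    ), call. = FALSE)
  }
  w0 <- 2 * pi * line_freq / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  # pad by periodic extension at the line period: the line component then
  # continues smoothly across the junctions, so the high-Q notch does not
  # ring into the record; edge transients die out inside the pad.
  x <- record$uv
  n <- length(x)
  cyc <- (1:20) * fs / line_freq # extension period: whole line cycles,
  m <- which.min(abs(cyc - round(cyc))) # chosen to be near-integer samples
  period <- max(1L, as.integer(round(cyc[m])))
  pad <- min(n - n %% period, period * ceiling(2 * fs / period))
  i <- (1L - pad):(n + pad)
  i <- ifelse(i < 1L, i + period * ceiling((1L - i) / period), i)
  i <- ifelse(i > n, i - period * ceiling((i - n) / period), i)
  y <- signal::filtfilt(signal::Arma(b = b, a = a), x[i])[pad + seq_len(n)]
  ecg_with_samples(record, y)
}

#' Remove baseline wander with a cubic spline through isoelectric points
#'
#' One isoelectric knot per beat is taken as the mean amplitude over a 20 ms
#' window before each R peak: inside the TP interval (ending `RR - 750` ms
#' before the R peak, capped at 250 ms) when the rhythm is slow enough, and
#' falling back to the PR segment (ending 66 ms before the R peak) at fast
#' rates where no TP interval exists. A cubic interpolating spline through
#' the knots estimates the wandering baseline, which is subtracted; beyond
#' the first/last knot the estimate is held constant.
#'
#' @param record An [ecg_record()].
#' @param peaks An `r_peaks` result from [detect_r_peaks()] (>= 4 beats).
#' @return A baseline-corrected [ecg_record()].
#' @export
remove_baseline <- function(record, peaks) {
  stopifnot(is_ecg_record(record))
  fs <- ecg_fs(record)
  idx <- r_peak_indices(peaks)
  if (length(idx) < 4L) {
    stop("baseline spline needs at least 4 beats", call. = FALSE)
  }
  x <- record$uv
  n <- length(x)
  win <- max(1L, round(0.020 * fs))
  rr_ms <- diff(idx) / fs * 1000
  rr_prev <- c(rr_ms[1], rr_ms) # first beat borrows the following interval
  lead_ms <- pmin(pmax(rr_prev - 750, 66), 250)
  knot_t <- numeric(length(idx))
  knot_v <- numeric(length(idx))
  for (i in seq_along(idx)) {
    hi <- idx[i] - round(lead_ms[i] / 1000 * fs)
    lo <- hi - win + 1L
    lo <- max(1L, lo)
    hi <- max(lo, min(n, hi))
    knot_t[i] <- (lo + hi) / 2
    knot_v[i] <- mean(x[lo:hi])
  }
  sf <- stats::splinefun(knot_t, knot_v, method = "natural")
  tgrid <- seq_len(n)
  base <- sf(pmin(pmax(tgrid, knot_t[1]), knot_t[length(knot_t)]))
  ecg_with_samples(record, x - base)
}

#' Suppress broadband noise by wavelet soft thresholding
#'
#' Four-level stationary (undecimated) wavelet transform with an orthogonal
#' 4-vanishing-moment (Daubechies) wavelet; the two finest detail levels
#' (roughly above fs/8 Hz) are soft-thresholded with the universal threshold
#' `scale * sigma * sqrt(2 log n)`, `sigma` estimated from the finest level
#' by the median absolute deviation. Coarser levels, which carry the T wave
#' (below 10 Hz), are untouched. The undecimated transform is
#' shift-invariant, so identical beats are denoised identically regardless
#' of their position in the record.
#'
#' @param record An [ecg_record()].
#' @param levels Decomposition depth.
#' @param shrink_levels How many of the finest detail levels to threshold.
#' @param threshold_scale Multiplier on the universal threshold; 0 is a
#'   no-op (perfect reconstruction).
#' @return A denoised [ecg_record()].
#' @export
wavelet_denoise <- function(record, levels = 4L, shrink_levels = 2L,
                            threshold_scale = 1) {
  stopifnot(is_ecg_record(record))
  x <- record$uv
  n <- length(x)
  if (n < 2L^levels) {
    stop(sprintf("record too short for a %d-level transform", levels),
      call. = FALSE
    )
  }
  dec <- swt_forward(x, levels)
  sigma <- stats::median(abs(dec$details[[1]])) / 0.6745
  thr <- threshold_scale * sigma * sqrt(2 * log(n))
  for (j in seq_len(min(shrink_levels, levels))) {
    dec$details[[j]] <- soft_threshold(dec$details[[j]], thr)
  }
  y <- swt_inverse(dec)
  ecg_with_samples(record, y)
}

#' Locate R peaks by wavelet modulus-maxima pairs
#'
#' Detail coefficients of the dyadic a-trous transform (quadratic-spline
#' wavelet, scales 2^1 to 2^4) act as smoothed derivatives: each QRS produces
#' an opposite-signed pair of modulus maxima whose zero-crossing marks the
#' R peak. Candidate pairs at scale 2^3 must exceed an adaptive threshold
#' (0.3 x the median modulus maximum within a 2 s neighbourhood) and be
#' confirmed at scale 2^2; a 200 ms refractory period keeps the strongest
#' candidate.
#'
#' @param record An [ecg_record()] (preprocessed; >= 2 beats expected).
#' @param max_pair_ms Maximum spacing of a modulus-maxima pair.
#' @return An `r_peaks` tibble with columns `peak` (sample index), `time`
#'   (s), and `rr_ms` (interval ending at that peak; `NA` for the first),
#'   plus summary attributes `mean_rr_ms` and `sd_rr_ms`.
#' @export
detect_r_peaks <- function(record, max_pair_ms = 120) {
  stopifnot(is_ecg_record(record))
  fs <- ecg_fs(record)
  x <- record$uv
  n <- length(x)
  W <- atrous_swt(x, levels = 4L)
  w2 <- W[, 2] # pairing scale: QRS slopes dominate, T waves are too smooth
  w3 <- W[, 3] # confirmation scale

  ext <- local_extrema(w2)
  if (!length(ext)) stop("no QRS candidates found (flat record?)", call. = FALSE)
  mag <- abs(w2[ext])
  # adaptive threshold: 0.3 x the largest modulus maximum within +/- 1 s
  # (the QRS pair dominates the transform at this scale)
  half <- round(1 * fs)
  brk <- pmin(pmax(ext %/% half, 0L), max(ext %/% half))
  seg_max <- tapply(mag, brk, max)
  seg_ids <- as.integer(names(seg_max))
  loc_max <- vapply(seq_along(ext), function(i) {
    ids <- seg_ids[abs(seg_ids - brk[i]) <= 1L]
    max(seg_max[as.character(ids)])
  }, numeric(1))
  keep <- mag > 0.3 * loc_max
  ext <- ext[keep]
  if (length(ext) < 2L) stop("no modulus-maxima pairs found", call. = FALSE)
  sgn <- sign(w2[ext])

  max_gap <- round(max_pair_ms / 1000 * fs)
  cand_pos <- integer(0)
  cand_amp <- numeric(0)
  i <- 1L
  while (i < length(ext)) {
    if (sgn[i] != sgn[i + 1L] && (ext[i + 1L] - ext[i]) <= max_gap) {
      seg <- ext[i]:ext[i + 1L]
      zc <- seg[which.min(abs(w2[seg]))]
      # confirm energy at the coarser scale near the crossing, relative to
      # the strongest scale-3 activity within +/- 1 s
      lo <- max(1L, zc - max_gap)
      hi <- min(n, zc + max_gap)
      nlo <- max(1L, zc - half)
      nhi <- min(n, zc + half)
      if (max(abs(w3[lo:hi])) > 0.3 * max(abs(w3[nlo:nhi]))) {
        # snap to the dominant signal extremum near the crossing
        slo <- max(1L, zc - round(0.025 * fs))
        shi <- min(n, zc + round(0.025 * fs))
        peak <- (slo:shi)[which.max(abs(x[slo:shi]))]
        cand_pos <- c(cand_pos, peak)
        cand_amp <- c(cand_amp, abs(w2[ext[i]]) + abs(w2[ext[i + 1L]]))
        i <- i + 2L
        next
      }
    }
    i <- i + 1L
  }
  if (!length(cand_pos)) stop("no R peaks detected", call. = FALSE)

  # refractory period: 200 ms, keep the stronger candidate
  refr <- round(0.2 * fs)
  ord <- order(cand_pos)
  cand_pos <- cand_pos[ord]
  cand_amp <- cand_amp[ord]
  keep <- rep(TRUE, length(cand_pos))
  last <- 1L
  for (j in seq_along(cand_pos)[-1]) {
    if (cand_pos[j] - cand_pos[last] < refr) {
      if (cand_amp[j] > cand_amp[last]) {
        keep[last] <- FALSE
        last <- j
      } else {
        keep[j] <- FALSE
      }
    } else {
      last <- j
    }
  }
  pos <- cand_pos[keep]
  if (length(pos) < 2L) stop("fewer than 2 R peaks detected", call. = FALSE)
  new_r_peaks(pos, fs)
}

#' @rdname detect_r_peaks
#' @param peak_indices Strictly increasing sample indices of R peaks, for
#'   constructing an `r_peaks` object from external annotations.
#' @param fs Sampling rate in Hz.
#' @export
r_peaks <- function(peak_indices, fs) new_r_peaks(peak_indices, fs)

new_r_peaks <- function(peak_indices, fs) {
  peak_indices <- as.integer(peak_indices)
  stopifnot(all(diff(peak_indices) > 0))
  rr <- diff(peak_indices) / fs * 1000
  out <- tibble::tibble(
    peak = peak_indices,
    time = (peak_indices - 1) / fs,
    rr_ms = c(NA_real_, rr)
  )
  structure(
    out,
    fs = fs,
    mean_rr_ms = mean(rr),
    sd_rr_ms = stats::sd(rr),
    class = c("r_peaks", class(out))
  )
}

#' @rdname detect_r_peaks
#' @param peaks An `r_peaks` object.
#' @export
r_peak_indices <- function(peaks) {
  stopifnot(inherits(peaks, "r_peaks"))
  peaks$peak
}

#' @rdname detect_r_peaks
#' @export
rr_intervals <- function(peaks) {
  stopifnot(inherits(peaks, "r_peaks"))
  peaks$rr_ms[-1]
}

local_extrema <- function(w) {
  n <- length(w)
  if (n < 3L) return(integer(0))
  d <- diff(w)
  which(d[-length(d)] * d[-1] < 0) + 1L
}

#' Heart-rate stability gate
#'
#' Records with large RR variation are excluded because a sudden rate change
#' alters T-wave morphology and mimics alternans. The gate passes when the
#' standard deviation of RR intervals is below 10% of their mean.
#'
#' @param peaks An `r_peaks` object with at least 2 RR intervals.
#' @param max_ratio Rejection threshold on sd(RR)/mean(RR).
#' @return A one-row tibble with `pass`, `ratio`, `mean_rr_ms`, `sd_rr_ms`.
#' @export
check_rr_stability <- function(peaks, max_ratio = 0.10) {
  rr <- rr_intervals(peaks)
  if (length(rr) < 2L) {
    stop("RR stability needs at least 2 intervals (3 beats)", call. = FALSE)
  }
  ratio <- stats::sd(rr) / mean(rr)
  tibble::tibble(
    pass = ratio < max_ratio,
    ratio = ratio,
    mean_rr_ms = mean(rr),
    sd_rr_ms = stats::sd(rr)
  )
}
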