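#' Continuous wavelet transform parameters
#'
#' The scalogram used for T-wave energies is computed with a complex Morlet
#' wavelet whose centre frequency at scale `a` (samples) is exactly
#' `fs / a` Hz, on a logarithmic frequency grid spanning the repolarization
#' band 0.5-10 Hz by default.
#'
#' @param freq_lo,freq_hi Frequency band bounds in Hz.
#' @param n_freqs Number of logarithmically spaced analysis frequencies.
#' @param support_sigmas Half-support of the discretized wavelet in units of
#'   its Gaussian envelope standard deviation.
#' @return A list of class `cwt_params`.
#' @export
cwt_params <- function(freq_lo = 0.5, freq_hi = 10, n_freqs = 32,
                       support_sigmas = 4) {
  stopifnot(freq_lo > 0, freq_hi > freq_lo, n_freqs >= 2)
  structure(
    list(
      freqs = exp(seq(log(freq_lo), log(freq_hi), length.out = n_freqs)),
      support_sigmas = support_sigmas
    ),
    class = "cwt_params"
  )
}

#' Continuous wavelet transform (complex Morlet)
#'
#' Discrete approximation of the CWT
#' `T(a,b) = a^(-1/2) * sum_t x(t) * Conj(psi((t - b)/a))` on the scale grid
#' mapped from `params$freqs`. Linear in the input; computed by FFT
#' convolution with zero padding (no circular wrap-around).
#'
#' @param x Numeric signal (amplitude sequence).
#' @param fs Sampling rate in Hz.
#' @param params A [cwt_params()] object.
#' @return A `scalogram`: list with complex coefficient matrix `coef`
#'   (n_freqs x length(x)), `freqs`, `scales`, and `fs`.
#' @export
cwt <- function(x, fs, params = cwt_params()) {
  stopifnot(inherits(params, "cwt_params"))
  x <- as.numeric(x)
  n <- length(x)
  scales <- morlet_scale_for_freq(params$freqs, fs)
  max_l <- ceiling(params$support_sigmas * max(scales))
  if (n < max(scales)) {
    stop(sprintf(
      "scale grid exceeds signal support: largest scale %.0f samples, signal %d",
      max(scales), n
    ), call. = FALSE)
  }
  nfft <- stats::nextn(n + 2L * max_l, 2L)
  xf <- stats::fft(c(x, rep(0, nfft - n)))
  coef <- matrix(0i, length(scales), n)
  for (s in seq_along(scales)) {
    ker <- morlet_kernel(scales[s], params$support_sigmas)
    l <- (length(ker) - 1L) %/% 2L
    kf <- stats::fft(c(ker, rep(0, nfft - length(ker))))
    conv <- stats::fft(xf * Conj(kf), inverse = TRUE) / nfft
    # kernel is conjugated and time-reversed by Conj(kf); centre alignment:
    coef[s, ] <- conv[((seq_len(n) - l - 1L) %% nfft) + 1L]
  }
  structure(
    list(coef = coef, freqs = params$freqs, scales = scales, fs = fs),
    class = "scalogram"
  )
}

#' Scalogram energy density and total T-wave energy
#'
#' The energy density is `E(a,b) = |T(a,b)|^2`; the total energy of a
#' delimited time-frequency region is the unweighted double sum of the
#' density over its scale x time grid. Scaling the signal by `c` scales the
#' energy by `c^2`.
#'
#' @param scalogram A `scalogram`, already restricted to the window and band
#'   of interest.
#' @return A nonnegative scalar energy (uV^2 per grid cell, arbitrary units).
#' @export
twave_energy <- function(scalogram) {
  stopifnot(inherits(scalogram, "scalogram"))
  if (length(scalogram$coef) == 0L) {
    stop("empty time-frequency region", call. = FALSE)
  }
  sum(Mod(scalogram$coef)^2)
}

#' @rdname twave_energy
#' @param x A `scalogram`.
#' @export
energy_density <- function(x) {
  stopifnot(inherits(x, "scalogram"))
  Mod(x$coef)^2
}

#' Per-beat T-wave energies
#'
#' Computes each T wave's total scalogram energy in the analysis band over
#' the full window. Every window receives identical treatment: optional
#' anti-aliased decimation to `analysis_fs` (the band tops out at 10 Hz, so
#' 125 Hz retains it with ample margin while keeping the transform cheap),
#' then
#' symmetric padding by half the largest wavelet support so edge bias is the
#' same for every beat and cancels in between-beat comparisons.
#'
#' @param twaves A `twave_matrix` from [extract_twaves()] (>= 2 rows).
#' @param params A [cwt_params()].
#' @param analysis_fs Internal sampling rate for the energy computation, in
#'   Hz; `NULL` disables decimation. The default keeps the anti-alias
#'   transition band well above the 10 Hz band edge.
#' @return A tibble with columns `beat` (original beat index), `parity`
#'   (`"odd"`/`"even"`), and `energy`.
#' @export
energy_series <- function(twaves, params = cwt_params(), analysis_fs = 125) {
  stopifnot(is_twave_matrix(twaves))
  if (nrow(twaves) < 2L) {
    stop("need at least 2 T waves for an energy series", call. = FALSE)
  }
  fs <- attr(twaves, "fs")
  w <- unclass(twaves)
  if (!is.null(analysis_fs) && analysis_fs < fs) {
    w <- decimate_rows(w, fs, analysis_fs)
    fs <- analysis_fs
  }
  m <- ncol(w)
  scales <- morlet_scale_for_freq(params$freqs, fs)
  max_l <- ceiling(params$support_sigmas * max(scales))
  pad <- max_l # half the largest wavelet support
  # nfft large enough that circular convolution equals linear convolution
  nfft <- stats::nextn(m + 2L * pad + 2L * max_l, 2L)

  # symmetric (mirror-tiled) extension, identical for every row; columns are
  # time, rows padded signals stacked for mvfft
  ext_idx <- extend_symmetric_index(m, pad)
  padded <- matrix(0, nfft, nrow(w))
  padded[seq_along(ext_idx), ] <- t(w[, ext_idx, drop = FALSE])
  xf <- stats::mvfft(padded)
  window_rows <- pad + seq_len(m)
  energy <- numeric(nrow(w))
  for (s in seq_along(scales)) {
    ker <- morlet_kernel(scales[s], params$support_sigmas)
    l <- (length(ker) - 1L) %/% 2L
    kf <- stats::fft(c(ker, rep(0, nfft - length(ker))))
    conv <- stats::mvfft(xf * Conj(kf), inverse = TRUE) / nfft
    rows <- ((window_rows - l - 1L) %% nfft) + 1L
    energy <- energy + colSums(Mod(conv[rows, , drop = FALSE])^2)
  }
  beats <- attr(twaves, "beat_index")
  tibble::tibble(
    beat = beats,
    parity = factor(ifelse(beats %% 2 == 1, "odd", "even"),
      levels = c("odd", "even")
    ),
    energy = energy
  )
}

# Column indices implementing a mirror-tiled (symmetric, period 2m)
# extension of a length-m window by `pad` samples on each side.
extend_symmetric_index <- function(m, pad) {
  p <- (1L - pad):(m + pad)
  q <- (p - 1L) %% (2L * m)
  ifelse(q < m, q + 1L, 2L * m - q)
}

# Anti-aliased decimation of each row by an integer factor: zero-phase FIR
# lowpass (cutoff 0.8 x new Nyquist) applied identically to every row.
decimate_rows <- function(w, fs, new_fs) {
  r <- fs / new_fs
  if (abs(r - round(r)) > 1e-9) {
    stop("`analysis_fs` must divide the record sampling rate", call. = FALSE)
  }
  r <- as.integer(round(r))
  if (r == 1L) return(w)
  cutoff <- 0.8 / r # fraction of original Nyquist
  fir <- signal::fir1(48, cutoff)
  m <- ncol(w)
  pad <- min(m - 1L, 60L)
  filt_row <- function(x) {
    xp <- c(x[(pad + 1):2], x, x[(m - 1):(m - pad)])
    y <- signal::filtfilt(fir, xp)
    y[pad + seq(1L, m, by = r)]
  }
  t(apply(w, 1L, filt_row))
}
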