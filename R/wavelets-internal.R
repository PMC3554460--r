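# Internal wavelet machinery: periodic Daubechies DWT (denoising), the
# dyadic a-trous transform with the quadratic-spline wavelet (R detection),
# and complex Morlet kernels (T-wave scalogram). Kept internal; user-facing
# surfaces live in preprocess.R and energy.R.

# Daubechies scaling filter with 4 vanishing moments (8 taps, sum = sqrt(2)).
DB4_H <- c(
  0.23037781330885523, 0.71484657055254153, 0.63088076792959036,
  -0.02798376941698385, -0.18703481171888114, 0.03084138183598697,
  0.03288301166698295, -0.01059740178499728
)

qmf <- function(h) rev(h) * (-1)^(seq_along(h) - 1)

soft_threshold <- function(x, thr) sign(x) * pmax(abs(x) - thr, 0)

# --- stationary (undecimated) wavelet transform, circular ------------------
#
# Shift-invariant counterpart of the DWT used for denoising: the transform
# commutes with circular shifts, so a strictly periodic signal yields
# strictly periodic coefficients and the denoised beats stay identical
# (up to record-edge effects). Exact reconstruction follows from the QMF
# identity |H|^2 + |G|^2 = 2.

# circular convolution with a filter dilated by `spacing` (taps at
# 0, spacing, 2*spacing, ...); adjoint = TRUE applies the time-reversed
# (synthesis) operator.
circ_dilated_fft <- function(n, f, spacing, adjoint = FALSE) {
  taps <- numeric(n)
  pos <- ((seq_along(f) - 1L) * spacing) %% n + 1L
  for (i in seq_along(f)) taps[pos[i]] <- taps[pos[i]] + f[i]
  ff <- stats::fft(taps)
  if (adjoint) Conj(ff) else ff
}

swt_forward <- function(x, levels, h = DB4_H) {
  g <- qmf(h)
  n <- length(x)
  xf <- stats::fft(x)
  details <- vector("list", levels)
  for (j in seq_len(levels)) {
    s <- 2L^(j - 1L)
    details[[j]] <- Re(stats::fft(xf * circ_dilated_fft(n, g, s),
      inverse = TRUE)) / n
    xf <- xf * circ_dilated_fft(n, h, s)
  }
  list(approx = Re(stats::fft(xf, inverse = TRUE)) / n, details = details)
}

swt_inverse <- function(decomp, h = DB4_H) {
  g <- qmf(h)
  n <- length(decomp$approx)
  af <- stats::fft(decomp$approx)
  for (j in rev(seq_along(decomp$details))) {
    s <- 2L^(j - 1L)
    df <- stats::fft(decomp$details[[j]])
    af <- (af * circ_dilated_fft(n, h, s, adjoint = TRUE) +
      df * circ_dilated_fft(n, g, s, adjoint = TRUE)) / 2
  }
  Re(stats::fft(af, inverse = TRUE)) / n
}

# --- a-trous transform (Mallat-Zhong quadratic-spline wavelet) -------------
#
# Detail coefficients behave like smoothed derivatives of the signal: a
# sharp upstroke-downstroke (the QRS) yields an opposite-signed pair of
# modulus maxima whose zero-crossing sits on the R peak. Filters:
# lowpass [1,3,3,1]/8, highpass [2,-2]; holes of 2^(j-1) zeros at level j.
# Kernels are applied centred so the transform is (half-sample) zero phase;
# the residual half-sample-per-level shift is accumulated and returned.

atrous_convolve <- function(x, kernel, spacing) {
  n <- length(x)
  taps <- which(kernel != 0)
  offs <- (taps - 1L) * spacing
  offs <- offs - floor(max(offs) / 2) # approximately centre the kernel
  out <- numeric(n)
  for (i in seq_along(taps)) {
    k <- offs[i]
    shifted <- if (k >= 0) {
      c(x[(k + 1L):n], rep(x[n], k))
    } else {
      c(rep(x[1], -k), x[1:(n + k)])
    }
    out <- out + kernel[taps[i]] * shifted
  }
  out
}

# Returns a matrix n x levels of detail coefficients W_{2^j}.
atrous_swt <- function(x, levels = 4L) {
  h <- c(1, 3, 3, 1) / 8
  g <- c(2, -2)
  n <- length(x)
  W <- matrix(0, n, levels)
  s <- x
  for (j in seq_len(levels)) {
    spacing <- 2L^(j - 1L)
    W[, j] <- atrous_convolve(s, g, spacing)
    s <- atrous_convolve(s, h, spacing)
  }
  W
}

# --- complex Morlet -------------------------------------------------------
#
# psi(t) = pi^(-1/4) exp(i w0 t) exp(-t^2/2) with w0 = 2*pi, so the centre
# frequency of scale `a` (in samples) is exactly fs / a Hz.
MORLET_W0 <- 2 * pi

morlet_kernel <- function(scale, support_sigmas = 4) {
  L <- ceiling(support_sigmas * scale)
  t <- (-L):L / scale
  pi^(-0.25) * exp(1i * MORLET_W0 * t - t^2 / 2) / sqrt(scale)
}

morlet_scale_for_freq <- function(freq_hz, fs) fs / freq_hz

morlet_freq_for_scale <- function(scale, fs) fs / scale
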