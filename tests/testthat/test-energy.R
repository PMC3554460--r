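test_that("the CWT is linear and zero maps to zero", {
  fs <- 100
  p <- cwt_params(0.5, 10, 12)
  t <- (0:599) / fs
  x <- sin(2 * pi * 3 * t)
  y <- cos(2 * pi * 1.2 * t) + 0.3 * sin(2 * pi * 7 * t)
  cx <- cwt(x, fs, p)$coef
  cy <- cwt(y, fs, p)$coef
  cxy <- cwt(x + y, fs, p)$coef
  expect_lt(max(Mod(cxy - cx - cy)) / max(Mod(cxy)), 1e-9)
  expect_equal(max(Mod(cwt(rep(0, 600), fs, p)$coef)), 0)
  # a scale grid the signal cannot support is refused
  expect_error(cwt(rnorm(50), fs, p), "support")
})

test_that("a tone's scalogram peaks at the matching frequency and agrees
           with direct quadrature", {
  fs <- 100
  p <- cwt_params(0.5, 10, 16)
  x <- sin(2 * pi * 3 * (0:799) / fs)
  sc <- cwt(x, fs, p)
  mid <- 300:500 # away from edges
  peak_freq <- sc$freqs[which.max(apply(Mod(sc$coef[, mid]), 1, max))]
  expect_equal(peak_freq, sc$freqs[which.min(abs(sc$freqs - 3))])

  # independent oracle: direct numerical quadrature of the transform
  # integral at several scales and locations
  for (s in c(4, 8, 12)) {
    for (b in c(350, 400, 450)) {
      a <- sc$scales[s]
      l <- ceiling(4 * a)
      tt <- (b - l):(b + l)
      tt <- tt[tt >= 1 & tt <= length(x)]
      psi <- pi^(-0.25) * exp(1i * 2 * pi * (tt - b) / a -
        ((tt - b) / a)^2 / 2) / sqrt(a)
      oracle <- sum(x[tt] * Conj(psi))
      expect_lt(Mod(sc$coef[s, b] - oracle) / Mod(oracle), 0.01)
    }
  }
})

test_that("scalogram energy is a nonnegative quadratic form", {
  fs <- 100
  p <- cwt_params(0.5, 10, 8)
  x <- sin(2 * pi * 2 * (0:399) / fs)
  sc <- cwt(x, fs, p)
  e1 <- twave_energy(sc)
  expect_gte(e1, 0)
  sc2 <- cwt(2 * x, fs, p)
  expect_equal(twave_energy(sc2), 4 * e1, tolerance = 1e-9)
  expect_equal(twave_energy(cwt(rep(0, 400), fs, p)), 0)
  expect_true(all(energy_density(sc) >= 0))
})

test_that("per-beat energies: identical beats tie exactly, alternans separates
           parities, scaling is quadratic", {
  tm <- default_beat_templates()[[1]]
  sim <- make_clean_ecg(tm, 24)
  pk <- r_peaks(sim$truth$r_samples, 500)
  tw <- extract_twaves(sim$record, pk)
  en <- energy_series(tw)
  expect_equal(nrow(en), 24)
  expect_equal(diff(range(en$energy)), 0) # identical rows -> identical energy

  # quadratic scaling through the whole energy path
  tw2 <- tw
  tw2[] <- 2 * unclass(tw)
  en2 <- energy_series(tw2)
  expect_equal(en2$energy, 4 * en$energy, tolerance = 1e-9)

  # alternans at 200 uV, no noise: odd and even energies disjoint
  sim_a <- simulate_twa_record(
    template = 1, n_beats = 24, k = 200,
    snr_db = NULL
  )
  tw_a <- extract_twaves(sim_a$record, r_peaks(sim_a$truth$r_samples, 500))
  en_a <- energy_series(tw_a)
  odd <- en_a$energy[en_a$parity == "odd"]
  even <- en_a$energy[en_a$parity == "even"]
  expect_true(max(odd) < min(even) || max(even) < min(odd))

  # single row is refused
  one <- tw[1, , drop = FALSE]
  attr(one, "beat_index") <- 1L
  attr(one, "fs") <- 500
  class(one) <- class(tw)
  expect_error(energy_series(one), "at least 2")
})

test_that("energy is insensitive to content outside the 0.5-10 Hz band", {
  tm <- default_beat_templates()[[1]]
  sim <- make_clean_ecg(tm, 8)
  tw <- extract_twaves(sim$record, r_peaks(sim$truth$r_samples, 500))
  base <- energy_series(tw)$energy[1]
  # add a 25 Hz tone with RMS equal to the window's RMS
  row <- unclass(tw)[1, ]
  tone <- sin(2 * pi * 25 * (seq_along(row) - 1) / 500)
  tone <- tone * rms(row) / rms(tone)
  tw2 <- tw
  tw2[] <- matrix(rep(row + tone, nrow(tw)), nrow(tw), byrow = TRUE)
  perturbed <- energy_series(tw2)$energy[1]
  expect_lt(abs(perturbed - base) / base, 0.05)
})

test_that("T-wave energies and the detection call are robust to small
           RT-interval shifts", {
  fx <- fix_noisy_analysis()
  pre <- preprocess_ecg(fx$sim$record)
  pk <- r_peak_indices(pre$peaks)
  base <- energy_series(extract_twaves(pre$record, r_peaks(pk, 500)))
  base_call <- classify_twa(base)$twa_present
  for (shift in c(-5L, 5L)) { # +/- 10 ms
    en <- energy_series(extract_twaves(pre$record, r_peaks(pk + shift, 500)))
    expect_lt(abs(mean(en$energy) - mean(base$energy)) / mean(base$energy),
      0.015)
    expect_equal(classify_twa(en)$twa_present, base_call)
  }
})
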