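test_that("notch filter removes the line tone and preserves the passband", {
  fs <- 500
  t <- (0:4999) / fs
  tone50 <- ecg_record(sin(2 * pi * 50 * t + 0.7), fs)
  tone5 <- ecg_record(sin(2 * pi * 5 * t), fs)
  out50 <- notch_filter(tone50, line_freq = 50)
  out5 <- notch_filter(tone5, line_freq = 50)
  # FFT-amplitude oracle: residual RMS of the pure line tone
  expect_lt(rms(out50$uv) / rms(tone50$uv), 0.01)
  expect_lt(abs(rms(out5$uv) / rms(tone5$uv) - 1), 0.01)
  expect_equal(nrow(out50), nrow(tone50))
  expect_equal(ecg_fs(out50), fs)
  # linearity: zero in, zero out
  zero <- ecg_record(rep(0, 1000), fs)
  expect_equal(notch_filter(zero)$uv, rep(0, 1000))
  # precondition
  expect_error(notch_filter(ecg_record(rnorm(100), fs = 80), 50), "too low")
  expect_error(notch_filter(tone50, line_freq = 55), "50 or 60")
})

test_that("baseline spline removes slow wander and leaves flat records alone", {
  tm <- default_beat_templates()[[1]]
  sim <- make_clean_ecg(tm, 16)
  pk <- r_peaks(sim$truth$r_samples, 500)

  # zero-baseline input is nearly unchanged
  out0 <- remove_baseline(sim$record, pk)
  expect_lt(max(abs(out0$uv - sim$record$uv)), 1)

  # 0.3 Hz, 300 uV wander: band-power oracle, >= 90% removed in [0, 0.45] Hz
  drift <- 300 * sin(2 * pi * 0.3 * (seq_len(nrow(sim$record)) - 1) / 500)
  rec <- ecg_record(sim$record$uv + drift, 500)
  out <- remove_baseline(rec, pk)
  bp <- function(v) {
    p <- Mod(stats::fft(v - mean(v)))^2
    f <- (seq_along(v) - 1) * 500 / length(v)
    sum(p[f > 0 & f <= 0.45])
  }
  expect_lt(bp(out$uv) / bp(rec$uv), 0.10)

  # < 4 beats is refused
  sim3 <- make_clean_ecg(tm, 3)
  expect_error(
    remove_baseline(sim3$record, r_peaks(sim3$truth$r_samples, 500)),
    "4 beats"
  )
})

test_that("wavelet denoising improves SNR and has a no-op limit", {
  tm <- default_beat_templates()[[1]]
  clean <- make_clean_ecg(tm, 16)$record$uv
  withr::local_seed(5)
  noise <- rnorm(length(clean))
  noise <- noise * sqrt(signal_power_t(clean) / mean(noise^2) / 100) # 20 dB
  noisy <- ecg_record(clean + noise, 500)
  den <- wavelet_denoise(noisy)
  snr <- function(est) {
    err <- est - clean
    10 * log10(signal_power_t(clean) / mean((err - mean(err))^2))
  }
  expect_gt(snr(den$uv), 20)
  expect_gt(snr(den$uv), snr(noisy$uv))

  # threshold scale 0 reconstructs the input exactly (up to fp error)
  ident <- wavelet_denoise(noisy, threshold_scale = 0)
  expect_lt(max(abs(ident$uv - noisy$uv)), 1e-8 * max(abs(noisy$uv)))

  # zero in, zero out; length preserved
  zero <- ecg_record(rep(0, 512), 500)
  expect_equal(wavelet_denoise(zero)$uv, rep(0, 512))
  expect_equal(nrow(den), length(clean))
})

test_that("R peaks are located at the true beats within tolerance", {
  tm <- default_beat_templates()[[2]]
  sim <- make_clean_ecg(tm, 100)
  det <- detect_r_peaks(sim$record)
  pos <- r_peak_indices(det)
  expect_equal(length(pos), 100)
  err_ms <- abs(pos - sim$truth$r_samples) / 500 * 1000
  expect_true(all(err_ms <= 10))

  # at 30 dB SNR: >= 99 of 100 peaks within 20 ms, no spurious extras
  noisy <- simulate_twa_record(
    template = 2, n_beats = 100, k = 0,
    snr_db = 30, seed = 21
  )
  pre <- preprocess_ecg(noisy$record)
  pos_n <- r_peak_indices(pre$peaks)
  match_err <- vapply(
    noisy$truth$r_samples,
    function(p) min(abs(pos_n - p)) / 500 * 1000, numeric(1)
  )
  expect_gte(sum(match_err <= 20), 99)
  spurious <- vapply(
    pos_n,
    function(p) min(abs(noisy$truth$r_samples - p)) / 500 * 1000, numeric(1)
  )
  expect_true(all(spurious <= 20))

  # flat record: detection error
  expect_error(detect_r_peaks(ecg_record(rep(0, 5000), 500)), "flat|no ")
})

test_that("RR stability gate applies the 10% coefficient-of-variation rule", {
  # constant RR 1000 ms
  pk <- r_peaks(seq(1, by = 500, length.out = 10), 500)
  st <- check_rr_stability(pk)
  expect_true(st$pass)
  expect_equal(st$ratio, 0)

  # alternating 600/1200 ms: ratio -> 300/900 = 1/3, fail
  steps <- rep(c(300, 600), 50)
  pk2 <- r_peaks(cumsum(c(1, steps)), 500)
  st2 <- check_rr_stability(pk2)
  expect_false(st2$pass)
  expect_equal(st2$ratio, 1 / 3, tolerance = 0.01)

  # mild variation passes: RR = 1000, 1010, 990, 1005 ms
  pk3 <- r_peaks(cumsum(c(1, c(1000, 1010, 990, 1005) / 2)), 500)
  st3 <- check_rr_stability(pk3)
  expect_true(st3$pass)
  expect_lt(st3$ratio, 0.10)

  # too few intervals
  expect_error(check_rr_stability(r_peaks(c(1, 501), 500)), "at least 2")
})

test_that("preprocessing is length- and fs-preserving and maps zero to zero", {
  sim <- simulate_twa_record(template = 3, n_beats = 16, k = 50, snr_db = 25, seed = 3)
  pre <- preprocess_ecg(sim$record)
  expect_equal(nrow(pre$record), nrow(sim$record))
  expect_equal(ecg_fs(pre$record), ecg_fs(sim$record))
  expect_true(pre$stability$pass)
})
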