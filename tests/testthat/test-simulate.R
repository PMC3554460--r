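test_that("clean ECG is a periodic repetition with known fiducials", {
  tm <- default_beat_templates()[[1]]
  sim <- make_clean_ecg(tm, 50)
  expect_equal(nrow(sim$record), 50 * 500) # 50 s at 500 Hz
  expect_equal(length(sim$truth$r_samples), 50)
  expect_equal(diff(sim$truth$r_samples), rep(500, 49))
  # all T waves identical by construction
  tw <- extract_twaves(sim$record, r_peaks(sim$truth$r_samples, 500))
  expect_equal(max(apply(unclass(tw), 2, function(c) diff(range(c)))), 0)
  expect_error(make_clean_ecg(numeric(0), 10), "empty")
})

test_that("alternans waveforms are unit-peak and mostly inside the band", {
  g <- make_alternans_waveform("gaussian", 40, 500)
  d <- make_alternans_waveform("gaussian_derivative", 40, 500)
  expect_equal(length(g), 200)
  expect_equal(max(abs(g)), 1)
  expect_equal(max(abs(d)), 1)
  # gaussian is symmetric with its peak at the window centre
  expect_lte(abs(which.max(g) - 100.5), 1)
  expect_equal(as.numeric(g), rev(as.numeric(g)), tolerance = 0.05)
  # derivative kind is one-sided (first half-lobe)
  expect_true(all(d[101:200] == 0))
  # the detector's band sees the bulk of the injected energy
  expect_gt(band_power_frac(as.numeric(g), 500, 0.5, 10), 0.80)
  expect_gt(band_power_frac(as.numeric(d), 500, 0.5, 10), 0.80)
  expect_error(make_alternans_waveform("gaussian", 500, 500), "width_ms")
})

test_that("alternans injection modifies every second beat by k at the T peak", {
  tm <- default_beat_templates()[[2]]
  clean <- make_clean_ecg(tm, 16)
  wf <- make_alternans_waveform("gaussian", fs = 500)
  pert <- add_alternans(clean, wf, k = 200)
  # T-window maxima of consecutive beats differ by exactly k
  tw <- extract_twaves(pert$record, r_peaks(pert$truth$r_samples, 500))
  maxima <- apply(unclass(tw), 1, max)
  expect_equal(
    abs(diff(maxima))[1:14],
    rep(200, 14),
    tolerance = 1e-9
  )
  # truth bookkeeping matches the modified beats
  expect_equal(pert$truth$alternans$k, 200)
  expect_equal(pert$truth$alternans$modified_beats, seq(2, 16, by = 2))
  # k = 0 leaves the record unchanged
  same <- add_alternans(clean, wf, k = 0)
  expect_equal(same$record$uv, clean$record$uv)
})

test_that("noise surrogates have their class's spectral signature", {
  n <- 1e5
  # white: vanishing autocorrelation at positive lags
  w <- make_noise("white", n, 500, seed = 1)
  ac <- stats::acf(w, lag.max = 5, plot = FALSE)$acf[-1]
  expect_true(all(abs(ac) < 0.05))
  expect_equal(rms(w), 1, tolerance = 1e-9)

  # baseline wander: >= 95% of power below 0.5 Hz
  bw <- make_noise("baseline_wander", n, 500, seed = 2)
  expect_gt(band_power_frac(bw, 500, 0, 0.5, nfft = n), 0.95)

  # muscle: dominated by the 20-100 Hz band
  mu <- make_noise("muscle", n, 500, seed = 3)
  expect_gt(band_power_frac(mu, 500, 18, 102, nfft = n), 0.9)

  # determinism: same seed, same sequence; RNG state is restored
  before <- runif(1)
  expect_equal(
    make_noise("electrode_motion", 1000, 500, seed = 9),
    make_noise("electrode_motion", 1000, 500, seed = 9)
  )
  expect_error(make_noise("pink", 100, 500), "arg")
})

test_that("SNR mixing hits the target power ratio", {
  sim <- simulate_twa_record(template = 1, n_beats = 16, k = 50, snr_db = NULL)
  noise <- mixed_noise(nrow(sim$record), 500, seed = 4)
  mixed <- mix_to_snr(sim, noise, 30)
  expect_equal(mixed$truth$snr_db, 30, tolerance = 0.01)
  # l ratio between 20 and 40 dB targets on the same noise is exactly 10
  l20 <- mix_to_snr(sim, noise, 20)$truth$noise_factor
  l40 <- mix_to_snr(sim, noise, 40)$truth$noise_factor
  expect_equal(l20 / l40, 10, tolerance = 1e-9)
  # degenerate noise is refused
  expect_error(mix_to_snr(sim, rep(0, nrow(sim$record)), 30), "zero-power")
  # absent target leaves the record unchanged
  expect_equal(mix_to_snr(sim, noise, NULL)$record$uv, sim$record$uv)
})

test_that("the factorial grid has the design's structure and determinism", {
  grid <- build_grid(seed = 5)
  expect_equal(nrow(grid), 250)
  expect_equal(as.integer(table(grid$snr_db)), rep(50L, 5))
  expect_equal(as.integer(table(grid$k)), rep(50L, 5))
  expect_equal(as.integer(table(grid$waveform)), rep(125L, 2))
  expect_equal(dplyr::n_distinct(grid$seed), 250)
  expect_error(build_grid(n_templates = 4), "exactly 5")

  # realized cells carry complete truth metadata and are reproducible
  cell <- grid[17, ]
  r1 <- realize_grid_cell(cell)
  r2 <- realize_grid_cell(cell)
  expect_equal(r1$record$uv, r2$record$uv)
  expect_equal(r1$truth$alternans$k, cell$k)
  expect_equal(r1$truth$snr_db, cell$snr_db, tolerance = 0.01)
  expect_length(r1$truth$r_samples, cell$n_beats)
})
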