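test_that("the template T wave is the pointwise mean", {
  tw <- structure(rbind(c(0, 2, 0), c(0, 4, 0)),
    beat_index = 1:2, fs = 500,
    class = c("twave_matrix", "matrix", "array")
  )
  expect_equal(template_twave(tw), c(0, 3, 0))
  # identical rows reproduce the row
  twi <- tw
  twi[] <- rbind(c(1, 5, 2), c(1, 5, 2))
  expect_equal(template_twave(twi), c(1, 5, 2))
  # alternating T and T + delta -> T + delta/2
  t0 <- c(10, 30, 10)
  delta <- c(0, 8, 0)
  tw4 <- tw
  tw4 <- structure(rbind(t0, t0 + delta, t0, t0 + delta),
    beat_index = 1:4, fs = 500,
    class = c("twave_matrix", "matrix", "array")
  )
  expect_equal(template_twave(tw4), t0 + delta / 2)
})

test_that("ACI is a normalized projection with the expected scaling", {
  tm <- c(3, -1, 2, 0.5)
  expect_equal(aci(tm, tm), 1)
  for (c_ in c(-1, 0, 0.5, 1, 2)) {
    expect_equal(aci(c_ * tm, tm), c_, tolerance = 1e-12)
  }
  expect_equal(aci(c(0, 1), c(1, 0)), 0) # orthogonal
  expect_error(aci(c(1, 2), c(0, 0)), "degenerate")
})

test_that("episode delineation applies the 7-beat alternation rule", {
  expect_equal(nrow(find_episodes(rep(1, 20))), 0) # no deviation at all
  ep <- find_episodes(rep(c(1.1, 0.9), 4)) # 8 alternating beats
  expect_equal(ep$start_beat, 1)
  expect_equal(ep$stop_beat, 8)
  # 6 alternating beats then constant: too short
  expect_equal(nrow(find_episodes(c(rep(c(1.1, 0.9), 3), rep(1, 6)))), 0)
  # ACI = 1 breaks a run
  aci_br <- c(rep(c(1.1, 0.9), 4), 1, rep(c(1.1, 0.9), 4))
  ep_br <- find_episodes(aci_br)
  expect_equal(nrow(ep_br), 2)
  expect_equal(ep_br$n_beats, c(8, 8))
})

test_that("episode finder agrees with a brute-force scan", {
  withr::local_seed(99)
  for (rep in 1:40) {
    n <- sample(7:50, 1)
    aci <- 1 + sample(c(-0.1, 0, 0.1), n, replace = TRUE) *
      stats::runif(n, 0.5, 1.5)
    got <- find_episodes(aci)
    want <- brute_episodes(aci)
    expect_equal(got$start_beat, want$start_beat, info = paste("rep", rep))
    expect_equal(got$stop_beat, want$stop_beat, info = paste("rep", rep))
  }
})

test_that("ACA converts ACI deviations to microvolts", {
  tm <- c(10, 20, 10)
  expect_equal(aca(1, tm), 0)
  expect_equal(aca(1.1, tm), 2 * 0.1 * 600 / 40) # 3.0 uV
  expect_equal(aca(0.9, tm), 3.0) # symmetric in the deviation
  expect_equal(aca(1.1, 2 * tm), 2 * aca(1.1, tm)) # linear in template scale
  expect_error(aca(1.1, c(0, 0, 0)), "degenerate")
})

test_that("mean ACA averages per-beat amplitudes, preferring episode beats", {
  expect_equal(mean_aca(c(3, 3)), 3)
  expect_equal(mean_aca(c(0, 6)), 3)
  ep <- tibble::tibble(start_beat = 1L, stop_beat = 8L, n_beats = 8L)
  expect_equal(mean_aca(c(rep(4, 8), rep(100, 2)), beats = 1:10, episodes = ep), 4)
  expect_error(mean_aca(numeric(0)), "empty")
})

test_that("noise-free quantification is linear in the alternans level", {
  ratios <- vapply(c(10, 20, 50, 100, 200), function(k) {
    sim <- simulate_twa_record(
      template = 1, n_beats = 32, k = k,
      snr_db = NULL
    )
    tw <- extract_twaves(sim$record, r_peaks(sim$truth$r_samples, 500))
    quantify_twa(tw)$mean_aca / k
  }, numeric(1))
  expect_lt((max(ratios) - min(ratios)) / mean(ratios), 0.02)
})

test_that("quantification of a noisy alternans record is coherent", {
  res <- fix_noisy_analysis()$res
  prof <- res$profile
  expect_s3_class(prof, "alternans_profile")
  expect_true(all(prof$beats$aca >= 0))
  expect_true(all(prof$episodes$n_beats >= 7))
  expect_gt(nrow(prof$episodes), 0) # strong alternans forms episodes
  g <- glance(prof)
  expect_equal(g$n_beats, nrow(tidy(prof)))
  expect_equal(g$mean_aca, prof$mean_aca)
})
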