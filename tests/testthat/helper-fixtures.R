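# Shared fixtures, built in code. Heavier shared objects are memoised in
# this environment so several test files can reuse one computation.
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# A small analyzed record: template 1, 32 beats, k = 100 uV at 30 dB.
fix_noisy_analysis <- function() {
  fixture("noisy_analysis", function() {
    sim <- simulate_twa_record(
      template = 1, n_beats = 32, k = 100,
      snr_db = 30, seed = 11
    )
    list(sim = sim, res = analyze_twa(sim$record, quantify = "always"))
  })
}

# Exact two-sided rank-sum p-value by enumeration over all rank assignments
# (independent oracle; no ties assumed).
enum_rank_sum_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  sets <- utils::combn(length(pooled), n1)
  u_all <- apply(sets, 2, function(s) sum(r[s]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# Brute-force episode finder: maximal windows of length >= min_len where
# sign(aci - 1) is nonzero and strictly alternating.
brute_episodes <- function(aci, min_len = 7L) {
  n <- length(aci)
  s <- sign(aci - 1)
  ok_win <- function(i, j) {
    if (any(s[i:j] == 0)) {
      return(FALSE)
    }
    j == i || all(s[(i + 1):j] == -s[i:(j - 1)])
  }
  wins <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (j - i + 1 >= min_len && ok_win(i, j)) {
        maximal <- (i == 1 || !ok_win(i - 1, j)) && (j == n || !ok_win(i, j + 1))
        if (maximal) wins[[length(wins) + 1]] <- c(i, j)
      }
    }
  }
  if (!length(wins)) {
    return(tibble::tibble(
      start_beat = integer(0), stop_beat = integer(0),
      n_beats = integer(0)
    ))
  }
  m <- do.call(rbind, wins)
  tibble::tibble(
    start_beat = m[, 1], stop_beat = m[, 2],
    n_beats = m[, 2] - m[, 1] + 1L
  )
}

# FFT band power of a signal between f_lo and f_hi (Hz), zero-padded for
# resolution.
band_power_frac <- function(x, fs, f_lo, f_hi, nfft = 2^14) {
  xp <- c(x, rep(0, max(0, nfft - length(x))))
  p <- Mod(stats::fft(xp))^2
  f <- (seq_along(xp) - 1) * fs / length(xp)
  keep <- f <= fs / 2
  sum(p[keep & f >= f_lo & f <= f_hi]) / sum(p[keep])
}

rms <- function(x) sqrt(mean(x^2))

signal_power_t <- function(x) {
  x <- x - mean(x)
  mean(x^2)
}
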