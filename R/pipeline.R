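#' Analysis configuration
#'
#' All tunable constants of the combined algorithm in one place. Defaults
#' follow the method's stated constants: a 400 ms T-wave window, the
#' 0.5-10 Hz T-wave band, detection at `alpha = 0.05`, and episodes of at
#' least 7 alternating beats.
#'
#' @param line_freq Mains frequency in Hz (50 or 60).
#' @param notch_q Notch quality factor.
#' @param denoise_levels,denoise_shrink,denoise_scale Wavelet-denoise depth,
#'   number of thresholded fine levels, and threshold multiplier.
#' @param window_ms T-wave window width (ms).
#' @param guard_ms Clearance required before the next R peak (ms).
#' @param onset_mode T-wave onset rule; see [twave_onset()].
#' @param freq_lo,freq_hi,n_freqs CWT band and grid; see [cwt_params()].
#' @param analysis_fs Internal rate for energy computation (Hz).
#' @param alpha Detection significance level.
#' @param episode_min Minimum episode length (beats).
#' @param template_stat,aca_over Quantification options; see
#'   [quantify_twa()].
#' @param rr_max_ratio RR-stability gate threshold on sd(RR)/mean(RR).
#' @return A named list of class `twa_config`.
#' @export
twa_config <- function(line_freq = 50, notch_q = 30,
                       denoise_levels = 4L, denoise_shrink = 2L,
                       denoise_scale = 1,
                       window_ms = 400, guard_ms = 40,
                       onset_mode = "sqrt",
                       freq_lo = 0.5, freq_hi = 10, n_freqs = 32,
                       analysis_fs = 125,
                       alpha = 0.05, episode_min = 7L,
                       template_stat = "mean", aca_over = "episodes",
                       rr_max_ratio = 0.10) {
  structure(
    list(
      line_freq = line_freq, notch_q = notch_q,
      denoise_levels = denoise_levels, denoise_shrink = denoise_shrink,
      denoise_scale = denoise_scale,
      window_ms = window_ms, guard_ms = guard_ms, onset_mode = onset_mode,
      freq_lo = freq_lo, freq_hi = freq_hi, n_freqs = n_freqs,
      analysis_fs = analysis_fs,
      alpha = alpha, episode_min = episode_min,
      template_stat = template_stat, aca_over = aca_over,
      rr_max_ratio = rr_max_ratio
    ),
    class = c("twa_config", "list")
  )
}

#' Fixed preprocessing pipeline
#'
#' Applies, in order: power-line notch, R-peak detection, cubic-spline
#' baseline removal, wavelet denoising, a second R-peak pass on the cleaned
#' signal, and the RR-stability gate. The order is fixed; records failing
#' the gate are reported with `pass = FALSE`, not silently analyzed.
#'
#' @param record An [ecg_record()].
#' @param config A [twa_config()].
#' @return A list with `record` (cleaned), `peaks` (`r_peaks`), and
#'   `stability` (tibble from [check_rr_stability()]).
#' @export
preprocess_ecg <- function(record, config = twa_config()) {
  rec <- notch_filter(record, line_freq = config$line_freq, q = config$notch_q)
  peaks0 <- detect_r_peaks(rec)
  if (length(r_peak_indices(peaks0)) >= 4L) {
    rec <- remove_baseline(rec, peaks0)
  }
  rec <- wavelet_denoise(rec,
    levels = config$denoise_levels,
    shrink_levels = config$denoise_shrink,
    threshold_scale = config$denoise_scale
  )
  peaks <- detect_r_peaks(rec)
  stability <- check_rr_stability(peaks, max_ratio = config$rr_max_ratio)
  list(record = rec, peaks = peaks, stability = stability)
}

#' Run the full combined algorithm on one record
#'
#' Preprocessing, T-wave extraction, per-beat scalogram energies, rank-sum
#' detection, and (on positive records) correlation-based quantification.
#' Records failing the RR-stability gate return `status = "rejected_rr"`
#' without a detection decision.
#'
#' @param record An [ecg_record()].
#' @param config A [twa_config()].
#' @param quantify `"auto"` (quantify only when detection is positive),
#'   `"always"`, or `"never"`.
#' @return A `twa_analysis` object with fields `status` (`"twa"`,
#'   `"no_twa"`, or `"rejected_rr"`), `detection`, `profile`, `twaves`,
#'   `peaks`, `stability`, and `config`.
#' @export
analyze_twa <- function(record, config = twa_config(),
                        quantify = c("auto", "always", "never")) {
  quantify <- match.arg(quantify)
  pre <- preprocess_ecg(record, config)
  out <- list(
    config = config, peaks = pre$peaks, stability = pre$stability,
    detection = NULL, profile = NULL, twaves = NULL
  )
  if (!pre$stability$pass) {
    out$status <- "rejected_rr"
    return(structure(out, class = "twa_analysis"))
  }
  twaves <- extract_twaves(pre$record, pre$peaks,
    window_ms = config$window_ms, guard_ms = config$guard_ms,
    onset_mode = config$onset_mode
  )
  params <- cwt_params(config$freq_lo, config$freq_hi, config$n_freqs)
  energies <- energy_series(twaves, params, analysis_fs = config$analysis_fs)
  detection <- classify_twa(energies, alpha = config$alpha)
  out$twaves <- twaves
  out$detection <- detection
  out$status <- if (detection$twa_present) "twa" else "no_twa"
  if (quantify == "always" || (quantify == "auto" && detection$twa_present)) {
    out$profile <- quantify_twa(twaves,
      min_episode = config$episode_min,
      template_stat = config$template_stat,
      aca_over = config$aca_over
    )
  }
  structure(out, class = "twa_analysis")
}

#' @export
print.twa_analysis <- function(x, ...) {
  cat(sprintf("<twa_analysis> status: %s\n", x$status))
  if (!is.null(x$detection)) print(x$detection)
  if (!is.null(x$profile)) print(x$profile)
  invisible(x)
}

#' Glance at a full analysis
#'
#' @param x A `twa_analysis`.
#' @param ... Unused.
#' @return One-row tibble: `status`, `p_value`, `twa_present`, `mean_aca`
#'   (NA when not quantified), `n_beats`, `rr_ratio`.
#' @export
glance.twa_analysis <- function(x, ...) {
  tibble::tibble(
    status = x$status,
    p_value = if (!is.null(x$detection)) x$detection$p_value else NA_real_,
    twa_present = if (!is.null(x$detection)) x$detection$twa_present else NA,
    mean_aca = if (!is.null(x$profile)) x$profile$mean_aca else NA_real_,
    n_beats = if (!is.null(x$twaves)) nrow(x$twaves) else NA_integer_,
    rr_ratio = x$stability$ratio
  )
}
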