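#' T-wave onset relative to the R peak
#'
#' An empirical rule ties the T-wave onset to the preceding RR interval:
#' `Ts = 40 + 1.33 * sqrt(RR)` ms with RR in ms (default), placing the onset
#' just after the ST segment (about 82 ms for RR = 1000 ms). The alternative
#' `mode = "literal"` uses `40 + 1.33 * RR`, which puts the onset beyond the
#' beat at normal rates and is provided for comparison only.
#'
#' @param rr_ms Preceding RR interval(s) in ms (> 200).
#' @param mode `"sqrt"` (default) or `"literal"`.
#' @return Onset(s) in ms after the R peak; monotone increasing in RR.
#' @examples
#' twave_onset(1000) # 82.06 ms
#' @export
twave_onset <- function(rr_ms, mode = c("sqrt", "literal")) {
  mode <- match.arg(mode)
  if (any(!is.finite(rr_ms)) || any(rr_ms <= 0)) {
    stop("`rr_ms` must be positive and finite", call. = FALSE)
  }
  switch(mode,
    sqrt = 40 + 1.33 * sqrt(rr_ms),
    literal = 40 + 1.33 * rr_ms
  )
}

#' Extract per-beat T-wave windows
#'
#' For each beat, a window of fixed width (default 400 ms) starting at
#' [twave_onset()] after the R peak delimits the whole T wave. Beats whose
#' window would run into the next QRS (closer than `guard_ms` before the
#' next R peak) or past the record end are dropped, not truncated, so all
#' rows have the same length; parity bookkeeping downstream uses the
#' original beat index, so a dropped beat does not flip the alternation
#' phase.
#'
#' @param record A preprocessed [ecg_record()].
#' @param peaks An `r_peaks` object for the record.
#' @param window_ms T-wave window width in ms.
#' @param guard_ms Minimum clearance between window end and the next R peak.
#' @param onset_mode Passed to [twave_onset()].
#' @return A `twave_matrix`: numeric matrix with one row per surviving beat
#'   and `window_ms * fs / 1000` columns, with attributes `beat_index`
#'   (original beat numbers), `onset_sample`, and `fs`.
#' @export
extract_twaves <- function(record, peaks, window_ms = 400, guard_ms = 40,
                           onset_mode = c("sqrt", "literal")) {
  stopifnot(is_ecg_record(record))
  onset_mode <- match.arg(onset_mode)
  fs <- ecg_fs(record)
  idx <- r_peak_indices(peaks)
  n <- nrow(record)
  m <- round(window_ms / 1000 * fs)
  guard <- round(guard_ms / 1000 * fs)

  rows <- list()
  beat_index <- integer(0)
  onset_sample <- integer(0)
  # beat k uses RR_k = interval from peak k to peak k+1; the last beat has
  # no following RR and uses the previous interval.
  for (k in seq_along(idx)) {
    rr_next <- if (k < length(idx)) (idx[k + 1L] - idx[k]) / fs * 1000 else NA
    rr_k <- if (!is.na(rr_next)) rr_next else (idx[k] - idx[k - 1L]) / fs * 1000
    if (rr_k <= 200) next
    onset <- idx[k] + round(twave_onset(rr_k, onset_mode) / 1000 * fs)
    end <- onset + m - 1L
    if (end > n) next
    if (k < length(idx) && end >= idx[k + 1L] - guard) next
    rows[[length(rows) + 1L]] <- record$uv[onset:end]
    beat_index <- c(beat_index, k)
    onset_sample <- c(onset_sample, onset)
  }
  if (length(rows) < 2L) {
    stop("fewer than 2 extractable T waves", call. = FALSE)
  }
  tw <- do.call(rbind, rows)
  structure(
    tw,
    beat_index = beat_index,
    onset_sample = onset_sample,
    fs = fs,
    window_ms = window_ms,
    class = c("twave_matrix", "matrix", "array")
  )
}

#' @rdname extract_twaves
#' @param x A `twave_matrix`.
#' @export
is_twave_matrix <- function(x) inherits(x, "twave_matrix")

#' Tidy a T-wave matrix into long format
#'
#' @param x A `twave_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `beat` (original beat index), `parity`,
#'   `time_ms` (within the window), and `uv`.
#' @export
tidy.twave_matrix <- function(x, ...) {
  fs <- attr(x, "fs")
  beats <- attr(x, "beat_index")
  tibble::tibble(
    beat = rep(beats, each = ncol(x)),
    parity = factor(ifelse(rep(beats, each = ncol(x)) %% 2 == 1, "odd", "even"),
      levels = c("odd", "even")
    ),
    time_ms = rep((seq_len(ncol(x)) - 1) / fs * 1000, times = nrow(x)),
    uv = as.vector(t(unclass(x)))
  )
}
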