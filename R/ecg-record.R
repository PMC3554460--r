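#' Construct a single-lead ECG record
#'
#' An `ecg_record` is a tibble with one row per sample and columns `time`
#' (seconds from record start) and `uv` (amplitude in microvolts), carrying
#' the sampling rate and optional amplitude resolution as attributes. All
#' amplitudes in the package are microvolts; conversion from acquisition
#' units happens at read time.
#'
#' @param uv Numeric vector of sample amplitudes in microvolts.
#' @param fs Sampling rate in Hz (scalar, > 0).
#' @param resolution Optional amplitude resolution in microvolts per
#'   least-significant bit; used only when writing quantized formats.
#' @param label Free-text label for the record.
#' @return A tibble of class `ecg_record` with columns `time` and `uv`.
#' @examples
#' rec <- ecg_record(sin(seq(0, 2 * pi, length.out = 500)), fs = 500)
#' ecg_fs(rec)
#' @export
ecg_record <- function(uv, fs, resolution = NULL, label = "") {
  uv <- as.numeric(uv)
  if (length(uv) < 2L) {
    stop("an ECG record needs at least 2 samples", call. = FALSE)
  }
  if (!all(is.finite(uv))) {
    stop("ECG samples must all be finite", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a single positive number (Hz)", call. = FALSE)
  }
  if (!is.null(resolution)) {
    resolution <- as.numeric(resolution)
    if (length(resolution) != 1L || !is.finite(resolution) || resolution <= 0) {
      stop("`resolution` must be a single positive number (uV/LSB)", call. = FALSE)
    }
  }
  out <- tibble::tibble(time = (seq_along(uv) - 1) / fs, uv = uv)
  structure(
    out,
    fs = as.numeric(fs),
    resolution = resolution,
    label = as.character(label)[1],
    class = c("ecg_record", class(out))
  )
}

#' @rdname ecg_record
#' @param x An object.
#' @export
is_ecg_record <- function(x) inherits(x, "ecg_record")

#' Accessors for ECG records
#'
#' @param record An [ecg_record()].
#' @return `ecg_samples()` the amplitude vector (uV); `ecg_fs()` the sampling
#'   rate (Hz); `ecg_resolution()` the resolution (uV/LSB) or `NULL`.
#' @export
ecg_samples <- function(record) {
  stopifnot(is_ecg_record(record))
  record$uv
}

#' @rdname ecg_samples
#' @export
ecg_fs <- function(record) {
  stopifnot(is_ecg_record(record))
  attr(record, "fs")
}

#' @rdname ecg_samples
#' @export
ecg_resolution <- function(record) {
  stopifnot(is_ecg_record(record))
  attr(record, "resolution")
}

# Rebuild a record with new samples, preserving metadata. Used by every
# length-preserving filter so fs/resolution/label survive the pipeline.
ecg_with_samples <- function(record, uv) {
  ecg_record(
    uv,
    fs = attr(record, "fs"),
    resolution = attr(record, "resolution"),
    label = attr(record, "label")
  )
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf(
    "<ecg_record> %d samples @ %g Hz (%.1f s)%s\n",
    nrow(x), attr(x, "fs"), nrow(x) / attr(x, "fs"),
    if (nzchar(attr(x, "label"))) paste0(" - ", attr(x, "label")) else ""
  ))
  NextMethod()
}
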