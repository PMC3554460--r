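#' Read an ECG record from disk
#'
#' Supports two interchange formats: a minimal WFDB pair (text `.hea` header
#' plus 16-bit little-endian `.dat`, amplitudes converted to microvolts using
#' the header gain) and plain CSV with one sample per line (optional single
#' header line `uV`), for which the sampling rate must be supplied.
#'
#' @param path Path to a `.hea` header, a `.dat` file, or a CSV file.
#' @param fs_hint Sampling rate in Hz, required for CSV input.
#' @return An [ecg_record()] in microvolts.
#' @export
read_ecg <- function(path, fs_hint = NULL) {
  if (!file.exists(path) && !file.exists(paste0(path, ".hea"))) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("hea", "dat") || file.exists(paste0(path, ".hea"))) {
    read_wfdb(sub("\\.(hea|dat)$", "", path))
  } else if (ext %in% c("csv", "txt", "")) {
    if (is.null(fs_hint)) {
      stop("CSV input needs `fs_hint` (sampling rate in Hz)", call. = FALSE)
    }
    read_ecg_csv(path, fs_hint)
  } else {
    stop(sprintf("unrecognised ECG format: .%s", ext), call. = FALSE)
  }
}

read_ecg_csv <- function(path, fs) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) && tolower(trimws(lines[1])) %in% c("uv", "\"uv\"")) {
    lines <- lines[-1]
  }
  uv <- suppressWarnings(as.numeric(lines))
  if (anyNA(uv)) {
    bad <- which(is.na(uv))[1]
    stop(sprintf("CSV sample %d is not numeric: '%s'", bad, lines[bad]),
      call. = FALSE
    )
  }
  ecg_record(uv, fs = fs, label = basename(path))
}

# Minimal WFDB format-16 reader: one signal, .hea text header + int16 .dat.
# Gain is ADC units per millivolt; physical uV = (adc - baseline)/gain * 1000.
read_wfdb <- function(stem) {
  hea <- paste0(stem, ".hea")
  if (!file.exists(hea)) stop(sprintf("missing header: %s", hea), call. = FALSE)
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  rec_tok <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(rec_tok) < 4L) {
    stop("WFDB header: record line needs 'name nsig fs nsamples'", call. = FALSE)
  }
  nsig <- as.integer(rec_tok[2])
  fs <- as.numeric(rec_tok[3])
  nsamp <- as.integer(rec_tok[4])
  if (is.na(fs) || fs <= 0) {
    stop("WFDB header: bad sampling frequency field", call. = FALSE)
  }
  if (!identical(nsig, 1L)) {
    stop("WFDB header: only single-signal records are supported", call. = FALSE)
  }
  sig_tok <- strsplit(trimws(lines[2]), "\\s+")[[1]]
  if (length(sig_tok) < 3L) {
    stop("WFDB header: signal line needs 'file format gain ...'", call. = FALSE)
  }
  fmt <- sig_tok[2]
  if (!identical(fmt, "16")) {
    stop(sprintf("WFDB signal format %s unsupported (need 16)", fmt), call. = FALSE)
  }
  # gain field may be "200", "200(0)" or "200(0)/mV"
  gain_field <- sub("/.*$", "", sig_tok[3])
  baseline <- 0
  if (grepl("\\(", gain_field)) {
    baseline <- as.numeric(sub("^.*\\(([-0-9.]+)\\).*$", "\\1", gain_field))
    gain_field <- sub("\\(.*$", "", gain_field)
  }
  gain <- as.numeric(gain_field)
  if (is.na(gain) || gain <= 0) {
    stop("WFDB header: bad gain field", call. = FALSE)
  }
  dat <- paste0(stem, ".dat")
  if (!file.exists(dat)) stop(sprintf("missing signal file: %s", dat), call. = FALSE)
  adc <- readBin(dat, what = "integer", size = 2L, signed = TRUE,
    endian = "little", n = nsamp)
  if (length(adc) < nsamp) {
    stop("WFDB signal file shorter than header nsamples", call. = FALSE)
  }
  uv <- (adc - baseline) / gain * 1000
  ecg_record(uv, fs = fs, resolution = 1000 / gain, label = basename(stem))
}

#' Write an ECG record to disk
#'
#' CSV output is one sample per line in microvolts with a `uV` header line.
#' WFDB output writes a minimal format-16 header/signal pair; samples are
#' quantized to the record's resolution (uV/LSB, default 5) so the stored
#' integers are `round(uv / resolution)`.
#'
#' @param record An [ecg_record()].
#' @param path Output path. For WFDB, the stem or `.hea` path.
#' @param format `"csv"` or `"wfdb"`.
#' @return The path written (header path for WFDB), invisibly.
#' @export
write_ecg <- function(record, path, format = c("csv", "wfdb")) {
  stopifnot(is_ecg_record(record))
  format <- match.arg(format)
  if (format == "csv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("uV", format(record$uv, digits = 15, trim = TRUE,
      scientific = FALSE)), con)
    return(invisible(path))
  }
  stem <- sub("\\.(hea|dat)$", "", path)
  res <- ecg_resolution(record)
  if (is.null(res)) res <- 5
  gain <- 1000 / res
  adc <- as.integer(round(record$uv / res))
  if (any(abs(adc) > 32767L)) {
    stop("samples exceed int16 range at this resolution", call. = FALSE)
  }
  name <- basename(stem)
  hea <- c(
    sprintf("%s 1 %s %d", name, format(ecg_fs(record), digits = 12), length(adc)),
    sprintf("%s.dat 16 %s(0)/mV 16 0 %d 0 0 ECG", name,
      format(gain, digits = 12), adc[1])
  )
  writeLines(hea, paste0(stem, ".hea"))
  writeBin(adc, paste0(stem, ".dat"), size = 2L, endian = "little")
  invisible(paste0(stem, ".hea"))
}

#' Write a structured analysis result to JSON
#'
#' Serializes detection results, alternans profiles, or full pipeline
#' results to a machine-readable JSON document. Detection-only results omit
#' the quantification keys. Non-finite numeric fields are refused.
#'
#' @param result A `twa_detection`, `alternans_profile`, or `twa_analysis`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_result <- function(result, path) {
  lst <- as_result_list(result)
  check_finite_result(lst, deparse(substitute(result)))
  jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read back a JSON analysis result
#'
#' @param path Path written by [write_result()].
#' @return A named list mirroring the JSON document.
#' @export
read_result <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

check_finite_result <- function(x, what) {
  rapply(x, function(v) {
    if (is.numeric(v) && length(v) && !all(is.finite(v))) {
      stop(sprintf("non-finite numeric value in result '%s'", what),
        call. = FALSE
      )
    }
    v
  }, how = "unlist")
  invisible(TRUE)
}

# Convert result objects to plain lists for JSON serialization.
as_result_list <- function(x) UseMethod("as_result_list")

#' @export
as_result_list.default <- function(x) {
  if (is.list(x)) lapply(x, as_result_list) else x
}

#' @export
as_result_list.data.frame <- function(x) as.data.frame(x)

#' @export
as_result_list.twa_detection <- function(x) {
  list(
    kind = "twa_detection",
    p_value = x$p_value,
    twa_present = x$twa_present,
    alpha = x$alpha,
    n_odd = x$n_odd,
    n_even = x$n_even,
    rank_statistic = x$statistic
  )
}

#' @export
as_result_list.alternans_profile <- function(x) {
  list(
    kind = "alternans_profile",
    template_uv = x$template,
    beats = as.data.frame(x$beats),
    episodes = as.data.frame(x$episodes),
    mean_aca_uv = x$mean_aca,
    mean_aca_all_uv = x$mean_aca_all
  )
}

#' @export
as_result_list.twa_analysis <- function(x) {
  out <- list(
    kind = "twa_analysis",
    status = x$status,
    config = x$config[!vapply(x$config, is.function, logical(1))],
    detection = if (!is.null(x$detection)) as_result_list(x$detection),
    quantification = if (!is.null(x$profile)) as_result_list(x$profile)
  )
  out[!vapply(out, is.null, logical(1))]
}
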