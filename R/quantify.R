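#' Template T wave
#'
#' Pointwise average of all extracted T waves. The arithmetic mean is the
#' default; a pointwise median is available for robustness experiments.
#'
#' @param twaves A `twave_matrix` (>= 2 rows).
#' @param stat `"mean"` or `"median"`.
#' @return Numeric vector of length `ncol(twaves)` (uV).
#' @export
template_twave <- function(twaves, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  if (!is_twave_matrix(twaves) || nrow(twaves) < 2L) {
    stop("need a twave_matrix with at least 2 rows", call. = FALSE)
  }
  w <- unclass(twaves)
  if (stat == "mean") colMeans(w) else apply(w, 2L, stats::median)
}

#' Alternans correlation index
#'
#' Normalized projection of a beat's T wave onto the template:
#' `ACI_i = sum(T_i * Tm) / sum(Tm^2)`. Equals 1 when the beat matches the
#' template, and `c` when the beat is `c` times the template.
#'
#' @param t_i Numeric T-wave vector (uV), or a matrix with one beat per row.
#' @param tm Template T wave from [template_twave()].
#' @return Dimensionless ACI value(s).
#' @export
aci <- function(t_i, tm) {
  denom <- sum(tm^2)
  if (denom <= 0) stop("degenerate (all-zero) template", call. = FALSE)
  if (is.matrix(t_i) || is_twave_matrix(t_i)) {
    w <- unclass(t_i)
    stopifnot(ncol(w) == length(tm))
    drop(w %*% tm) / denom
  } else {
    stopifnot(length(t_i) == length(tm))
    sum(t_i * tm) / denom
  }
}

#' Alternans episodes
#'
#' An episode is a maximal run of at least `min_len` consecutive T waves
#' whose ACI alternates strictly around 1: the sign of `ACI - 1` flips from
#' beat to beat, and `ACI = 1` (within `tol`) breaks a run. Runs are indexed
#' by the original beat numbers of the supplied series.
#'
#' @param aci_series Numeric ACI values in beat order.
#' @param beats Original beat indices (default sequential).
#' @param min_len Minimum episode length in beats.
#' @param tol Values of `|ACI - 1|` at or below `tol` count as no deviation.
#' @return A tibble with columns `start_beat`, `stop_beat`, `n_beats`.
#' @export
find_episodes <- function(aci_series, beats = seq_along(aci_series),
                          min_len = 7L, tol = 0) {
  stopifnot(length(beats) == length(aci_series))
  n <- length(aci_series)
  s <- sign(aci_series - 1)
  s[abs(aci_series - 1) <= tol] <- 0
  starts <- integer(0)
  stops <- integer(0)
  run_start <- 1L
  for (i in seq_len(n)) {
    ok <- i > run_start && s[i] != 0 && s[i - 1L] != 0 && s[i] == -s[i - 1L]
    if (i == run_start) ok <- s[i] != 0
    if (!ok) {
      if (i - run_start >= min_len) { # run ended at i-1
        starts <- c(starts, run_start)
        stops <- c(stops, i - 1L)
      }
      # a nonzero value can start a new run; zero cannot
      run_start <- if (s[i] != 0) i else i + 1L
    }
  }
  if (n + 1L - run_start >= min_len && run_start <= n) {
    starts <- c(starts, run_start)
    stops <- c(stops, n)
  }
  tibble::tibble(
    start_beat = beats[starts],
    stop_beat = beats[stops],
    n_beats = stops - starts + 1L
  )
}

#' Alternans amplitude in microvolts
#'
#' Converts an ACI deviation into an amplitude on the template's scale:
#' `ACA_i = 2 |ACI_i - 1| * sum(Tm^2) / sum(|Tm|)` (uV). The factor 2
#' accounts for the template sitting halfway between the two alternating
#' morphologies.
#'
#' @param aci_i ACI value(s).
#' @param tm Template T wave (uV).
#' @return Nonnegative amplitude(s) in uV.
#' @export
aca <- function(aci_i, tm) {
  denom <- sum(abs(tm))
  if (denom <= 0) stop("degenerate (all-zero) template", call. = FALSE)
  2 * abs(aci_i - 1) * sum(tm^2) / denom
}

#' Mean alternans amplitude
#'
#' Arithmetic mean of per-beat ACA values. When episodes are supplied the
#' mean is taken over beats inside episodes (the beats actually alternating)
#' and falls back to all beats when no episode was found.
#'
#' @param aca_series Per-beat ACA values (uV), in beat order.
#' @param beats Original beat indices matching `aca_series`.
#' @param episodes Optional episode tibble from [find_episodes()].
#' @return Mean ACA in uV.
#' @export
mean_aca <- function(aca_series, beats = seq_along(aca_series),
                     episodes = NULL) {
  if (!length(aca_series)) stop("empty ACA series", call. = FALSE)
  if (!is.null(episodes) && nrow(episodes)) {
    inside <- rep(FALSE, length(aca_series))
    for (e in seq_len(nrow(episodes))) {
      inside <- inside |
        (beats >= episodes$start_beat[e] & beats <= episodes$stop_beat[e])
    }
    if (any(inside)) {
      return(mean(aca_series[inside]))
    }
  }
  mean(aca_series)
}

#' Quantitative alternans measurement
#'
#' Runs the full correlation-based quantification on an extracted T-wave
#' matrix: template T wave, per-beat ACI and ACA, episode delineation, and
#' the mean alternans amplitude.
#'
#' @param twaves A `twave_matrix` from [extract_twaves()].
#' @param min_episode Minimum episode length in beats.
#' @param template_stat Passed to [template_twave()].
#' @param aca_over `"episodes"` (mean ACA over episode beats when present)
#'   or `"all"` (always all beats).
#' @return An `alternans_profile` with fields `template`, `beats` (tibble:
#'   `beat`, `parity`, `aci`, `aca`), `episodes`, `mean_aca`, and
#'   `mean_aca_all`.
#' @export
quantify_twa <- function(twaves, min_episode = 7L,
                         template_stat = c("mean", "median"),
                         aca_over = c("episodes", "all")) {
  aca_over <- match.arg(aca_over)
  tm <- template_twave(twaves, match.arg(template_stat))
  beats <- attr(twaves, "beat_index")
  aci_i <- aci(twaves, tm)
  aca_i <- aca(aci_i, tm)
  episodes <- find_episodes(aci_i, beats = beats, min_len = min_episode)
  m_all <- mean(aca_i)
  m_ep <- if (aca_over == "episodes") {
    mean_aca(aca_i, beats = beats, episodes = episodes)
  } else {
    m_all
  }
  structure(
    list(
      template = tm,
      beats = tibble::tibble(
        beat = beats,
        parity = factor(ifelse(beats %% 2 == 1, "odd", "even"),
          levels = c("odd", "even")
        ),
        aci = aci_i,
        aca = aca_i
      ),
      episodes = episodes,
      mean_aca = m_ep,
      mean_aca_all = m_all,
      fs = attr(twaves, "fs")
    ),
    class = "alternans_profile"
  )
}

#' @export
print.alternans_profile <- function(x, ...) {
  cat(sprintf(
    "<alternans_profile> %d beats, %d episode(s), mean ACA %.2f uV\n",
    nrow(x$beats), nrow(x$episodes), x$mean_aca
  ))
  invisible(x)
}

#' Tidiers for alternans profiles
#'
#' @param x An `alternans_profile`.
#' @param ... Unused.
#' @return `tidy()`: the per-beat tibble (`beat`, `parity`, `aci`, `aca`);
#'   `glance()`: a one-row summary.
#' @export
tidy.alternans_profile <- function(x, ...) x$beats

#' @rdname tidy.alternans_profile
#' @export
glance.alternans_profile <- function(x, ...) {
  tibble::tibble(
    n_beats = nrow(x$beats),
    n_episodes = nrow(x$episodes),
    episode_beats = sum(x$episodes$n_beats),
    mean_aca = x$mean_aca,
    mean_aca_all = x$mean_aca_all
  )
}
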