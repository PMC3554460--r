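#' Detection sensitivity against simulation truth
#'
#' For a set of records that all contain alternans by construction,
#' `Se = TP / (TP + FN) * 100`. Optional grouping columns give the
#' per-condition breakdown (by SNR, by alternans level).
#'
#' @param results Tibble with a logical `twa_present` column (one row per
#'   record, all truth-positive).
#' @param by Optional character vector of grouping columns in `results`.
#' @return A tibble with `tp`, `fn`, `n`, `se` (percent), one row overall or
#'   per group.
#' @export
sensitivity <- function(results, by = NULL) {
  if (!nrow(results)) stop("no detection results supplied", call. = FALSE)
  stopifnot("twa_present" %in% names(results))
  score <- function(d) {
    tibble::tibble(
      tp = sum(d$twa_present),
      fn = sum(!d$twa_present),
      n = nrow(d),
      se = 100 * sum(d$twa_present) / nrow(d)
    )
  }
  if (is.null(by)) {
    return(score(results))
  }
  results |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::group_modify(~ score(.x)) |>
    dplyr::ungroup()
}

#' Relative error of a measured alternans amplitude
#'
#' `RE = |A_twa - A_bar| / A_twa * 100`, the percent deviation of the
#' measured amplitude from the injected one.
#'
#' @param a_twa Injected (true) alternans amplitude in uV (> 0).
#' @param a_bar Measured amplitude in uV.
#' @return Relative error in percent (vectorized).
#' @export
relative_error <- function(a_twa, a_bar) {
  if (any(a_twa <= 0)) stop("`a_twa` must be positive", call. = FALSE)
  abs(a_twa - a_bar) / a_twa * 100
}

#' Spectral-method alternans estimate (comparator)
#'
#' Classical frequency-domain estimator on an aligned beat matrix: for each
#' sample position the periodogram of the across-beat series is computed
#' (`P(f) = |DFT|^2 / N^2`, `f` in cycles/beat), periodograms are averaged
#' over sample positions, and the alternans power is read at 0.5 cycles/beat
#' against a reference noise band. The alternans voltage is
#' `sqrt(max(P_0.5 - mu_noise, 0))`; the k-score is
#' `(P_0.5 - mu_noise) / sigma_noise`.
#'
#' @param twaves A `twave_matrix` (or plain beat-by-sample matrix) with at
#'   least 32 beats.
#' @param noise_band Frequency band (cycles/beat) used as the noise
#'   reference.
#' @return A list with `voltage` (uV), `k_score`, `p_alt`, `noise_mean`,
#'   `noise_sd`.
#' @export
spectral_method <- function(twaves, noise_band = c(0.33, 0.48)) {
  w <- unclass(twaves)
  if (!is.matrix(w)) w <- as.matrix(w)
  n <- nrow(w)
  if (n < 32L) stop("spectral method needs at least 32 beats", call. = FALSE)
  spec <- Mod(stats::mvfft(w))^2 / n^2 # per-column periodograms
  pbar <- rowMeans(spec)
  freq <- (seq_len(n) - 1) / n # cycles/beat
  i_alt <- which.min(abs(freq - 0.5))
  in_band <- freq >= noise_band[1] & freq <= noise_band[2]
  if (!any(in_band)) stop("empty noise band", call. = FALSE)
  mu <- mean(pbar[in_band])
  sdv <- stats::sd(pbar[in_band])
  p_alt <- pbar[i_alt]
  list(
    voltage = sqrt(max(p_alt - mu, 0)),
    k_score = if (sdv > 0) (p_alt - mu) / sdv else Inf,
    p_alt = p_alt,
    noise_mean = mu,
    noise_sd = sdv
  )
}

#' Paired comparison of the combined algorithm and the spectral method
#'
#' Joins per-record amplitude estimates from both methods, computes each
#' method's relative error against the injected level, and reports the
#' correlation between the two amplitude series.
#'
#' @param results Tibble with columns `k` (injected uV), `aca` (combined
#'   algorithm mean ACA, uV), and `asm` (spectral-method voltage, uV); at
#'   least 2 rows.
#' @return The tibble with added `re_ca` and `re_sm` columns (percent) and
#'   attribute `correlation`.
#' @export
compare_methods <- function(results) {
  need <- c("k", "aca", "asm")
  if (!all(need %in% names(results))) {
    stop("`results` needs columns k, aca, asm", call. = FALSE)
  }
  if (nrow(results) < 2L) {
    stop("need at least 2 paired records to compare methods", call. = FALSE)
  }
  out <- dplyr::mutate(results,
    re_ca = relative_error(k, .data$aca),
    re_sm = relative_error(k, .data$asm)
  )
  attr(out, "correlation") <- stats::cor(out$aca, out$asm)
  out
}

#' Run the combined algorithm over a simulation grid
#'
#' Realizes each grid cell, runs the full pipeline (preprocessing, T-wave
#' energies, rank-sum detection; optionally quantification), and returns one
#' row per cell with the decision and, when requested, the measured mean
#' ACA and the spectral-method voltage.
#'
#' @param grid Tibble from [build_grid()].
#' @param config A [twa_config()].
#' @param quantify Also run quantification and the spectral method per cell.
#' @param progress Print a line every 25 cells.
#' @return The grid tibble with added columns `status`, `p_value`,
#'   `twa_present`, and (if `quantify`) `mean_aca`, `sm_voltage`.
#' @export
run_twa_grid <- function(grid, config = twa_config(), quantify = FALSE,
                         progress = FALSE) {
  rows <- purrr::map(seq_len(nrow(grid)), function(i) {
    sim <- realize_grid_cell(grid[i, ])
    res <- analyze_twa(sim$record, config = config,
      quantify = if (quantify) "always" else "never")
    out <- tibble::tibble(
      status = res$status,
      p_value = if (!is.null(res$detection)) res$detection$p_value else NA_real_,
      twa_present = !is.null(res$detection) && res$detection$twa_present
    )
    if (quantify) {
      out$mean_aca <- if (!is.null(res$profile)) res$profile$mean_aca else NA_real_
      out$sm_voltage <- if (!is.null(res$twaves)) {
        spectral_method(res$twaves)$voltage
      } else {
        NA_real_
      }
    }
    if (progress && i %% 25 == 0) {
      message(sprintf("grid cell %d / %d", i, nrow(grid)))
    }
    out
  })
  dplyr::bind_cols(grid, dplyr::bind_rows(rows))
}
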