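#' Plot an ECG record
#'
#' @param object An [ecg_record()].
#' @param from,to Optional time range in seconds.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ecg_record <- function(object, from = NULL, to = NULL, ...) {
  df <- object
  if (!is.null(from)) df <- dplyr::filter(df, .data$time >= from)
  if (!is.null(to)) df <- dplyr::filter(df, .data$time <= to)
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$uv)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "amplitude (uV)") +
    ggplot2::theme_minimal()
}

#' Plot per-beat T-wave energies by parity
#'
#' Visualizes the two rank-sum groups: under alternans the odd- and
#' even-beat energy series separate.
#'
#' @param object A `twa_detection` from [classify_twa()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.twa_detection <- function(object, ...) {
  ggplot2::ggplot(
    object$energies,
    ggplot2::aes(.data$beat, .data$energy, colour = .data$parity)
  ) +
    ggplot2::geom_point(size = 0.9) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(
      x = "beat", y = "T-wave energy (a.u.)",
      title = sprintf(
        "%s (rank-sum p = %.3g)",
        if (object$twa_present) "TWA detected" else "no TWA", object$p_value
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot an alternans profile
#'
#' Per-beat ACI around 1 with detected episodes shaded, and the per-beat
#' alternans amplitude.
#'
#' @param object An `alternans_profile` from [quantify_twa()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.alternans_profile <- function(object, ...) {
  long <- tidyr::pivot_longer(object$beats, c("aci", "aca"),
    names_to = "measure", values_to = "value"
  )
  long$measure <- factor(long$measure, c("aci", "aca"),
    c("ACI", "ACA (uV)")
  )
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$beat, .data$value)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$parity), size = 0.8) +
    ggplot2::facet_wrap(~measure, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "beat", y = NULL) +
    ggplot2::theme_minimal()
  if (nrow(object$episodes)) {
    p <- p + ggplot2::geom_rect(
      data = object$episodes,
      ggplot2::aes(
        xmin = .data$start_beat, xmax = .data$stop_beat,
        ymin = -Inf, ymax = Inf
      ),
      inherit.aes = FALSE, alpha = 0.12, fill = "steelblue"
    )
  }
  p
}

#' Plot grid sensitivity breakdowns
#'
#' @param results Output of [run_twa_grid()].
#' @return A ggplot of detection rate by SNR and by alternans level.
#' @export
plot_grid_sensitivity <- function(results) {
  by_snr <- sensitivity(results, by = "snr_db") |>
    dplyr::mutate(condition = "SNR (dB)", level = .data$snr_db)
  by_k <- sensitivity(results, by = "k") |>
    dplyr::mutate(condition = "alternans level (uV)", level = .data$k)
  df <- dplyr::bind_rows(
    dplyr::select(by_snr, "condition", "level", "se"),
    dplyr::select(by_k, "condition", "level", "se")
  )
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$level), .data$se)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~condition, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "sensitivity (%)") +
    ggplot2::theme_minimal()
}
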