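#' Split per-beat energies into odd and even groups
#'
#' Grouping uses the original beat index (not row position), so a beat
#' dropped during T-wave extraction does not flip the alternation phase of
#' the beats that follow it.
#'
#' @param energies Tibble from [energy_series()] with columns `beat` and
#'   `energy`.
#' @return A list with numeric vectors `odd` and `even`.
#' @export
split_parity <- function(energies) {
  stopifnot(all(c("beat", "energy") %in% names(energies)))
  odd <- energies$energy[energies$beat %% 2 == 1]
  even <- energies$energy[energies$beat %% 2 == 0]
  if (length(odd) < 2L || length(even) < 2L) {
    stop("need at least 2 energies per parity group", call. = FALSE)
  }
  list(odd = odd, even = even)
}

#' Wilcoxon rank-sum test between two energy groups
#'
#' Two-sided Mann-Whitney test of the null that both groups come from the
#' same distribution: exact when the combined sample size is at most 30 and
#' there are no ties, tie-corrected normal approximation otherwise. When
#' every pooled value is identical the ranks carry no information and the
#' conventional p-value 1 is returned (clean periodic ECGs produce exactly
#' tied energies and must classify as alternans-free).
#'
#' Values closer than `tie_tol` (relative to the pooled magnitude) are
#' ranked as tied: differences at the floating-point noise floor carry no
#' physical information, and on noise-free periodic records they would
#' otherwise be ranked as if meaningful. Any real between-beat energy
#' difference is many orders of magnitude above this floor.
#'
#' @param x,y Numeric vectors (each length >= 2, finite).
#' @param exact_max Largest combined n for which the exact distribution is
#'   used.
#' @param tie_tol Relative tolerance below which pooled values are tied.
#' @return A list with `p_value`, `statistic` (the Mann-Whitney U of `x`),
#'   and `method`.
#' @export
rank_sum_test <- function(x, y, exact_max = 30, tie_tol = 1e-9) {
  if (length(x) < 2L || length(y) < 2L) {
    stop("both groups need at least 2 values", call. = FALSE)
  }
  if (!all(is.finite(c(x, y)))) {
    stop("energies must be finite", call. = FALSE)
  }
  pooled <- c(x, y)
  scale <- stats::median(abs(pooled))
  if (tie_tol > 0 && scale > 0) {
    pooled <- round(pooled / (scale * tie_tol)) * (scale * tie_tol)
    x <- pooled[seq_along(x)]
    y <- pooled[-seq_along(x)]
  }
  if (max(pooled) == min(pooled)) {
    return(list(
      p_value = 1,
      statistic = length(x) * length(y) / 2,
      method = "total tie"
    ))
  }
  ties <- anyDuplicated(pooled) > 0L
  use_exact <- (length(pooled) <= exact_max) && !ties
  ht <- suppressWarnings(stats::wilcox.test(
    x, y,
    alternative = "two.sided", exact = use_exact, correct = TRUE
  ))
  list(
    p_value = min(1, ht$p.value),
    statistic = unname(ht$statistic),
    method = if (use_exact) "exact" else "normal approximation"
  )
}

#' Qualitative T-wave alternans detection
#'
#' Splits the per-beat T-wave energies by beat parity and applies the
#' Wilcoxon rank-sum test; alternans is declared when the two groups differ
#' at the `alpha` level.
#'
#' @param energies Tibble from [energy_series()].
#' @param alpha Significance level (default 0.05).
#' @return A `twa_detection` object; see [glance.twa_detection()].
#' @export
classify_twa <- function(energies, alpha = 0.05) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha >= 0, alpha <= 1)
  groups <- split_parity(energies)
  test <- rank_sum_test(groups$odd, groups$even)
  structure(
    list(
      p_value = test$p_value,
      twa_present = test$p_value < alpha,
      alpha = alpha,
      n_odd = length(groups$odd),
      n_even = length(groups$even),
      statistic = test$statistic,
      method = test$method,
      energies = energies
    ),
    class = "twa_detection"
  )
}

#' @export
print.twa_detection <- function(x, ...) {
  cat(sprintf(
    "<twa_detection> %s (p = %.4g, alpha = %g; %d odd vs %d even beats)\n",
    if (x$twa_present) "TWA detected" else "no TWA",
    x$p_value, x$alpha, x$n_odd, x$n_even
  ))
  invisible(x)
}

#' Glance at a detection result
#'
#' @param x A `twa_detection`.
#' @param ... Unused.
#' @return A one-row tibble with `p_value`, `twa_present`, `statistic`,
#'   `n_odd`, `n_even`, and `alpha`.
#' @export
glance.twa_detection <- function(x, ...) {
  tibble::tibble(
    p_value = x$p_value,
    twa_present = x$twa_present,
    statistic = x$statistic,
    n_odd = x$n_odd,
    n_even = x$n_even,
    alpha = x$alpha
  )
}

#' @rdname glance.twa_detection
#' @export
tidy.twa_detection <- function(x, ...) x$energies
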