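#' Elastic modulus over a stretch window
#'
#' Slope of the least-squares line of true stress against engineering strain
#' (\eqn{\lambda - 1}) restricted to a stretch window. Over a narrow window
#' near \eqn{\lambda = 1} this approaches the initial tangent modulus.
#'
#' @param curve A [stress_stretch_curve()].
#' @param window Closed stretch interval `c(lo, hi)` containing at least two
#'   curve points.
#' @return Modulus in MPa.
#' @examples
#' curve <- generate_clean_curve(13.1, 0.21)
#' elastic_modulus(curve, c(1.0, 1.1))
#' @export
elastic_modulus <- function(curve, window) {
  stopifnot(length(window) == 2L, window[[1]] < window[[2]])
  sel <- curve$stretch >= window[[1]] - 1e-12 & curve$stretch <= window[[2]] + 1e-12
  if (sum(sel) < 2L) {
    abort(sprintf("Window [%.3g, %.3g] contains %d curve point(s); need >= 2.",
                  window[[1]], window[[2]], sum(sel)))
  }
  x <- curve$stretch[sel] - 1
  y <- curve$stress_MPa[sel]
  unname(coef(lm(y ~ x))[[2]])
}

#' Ultimate tensile stress
#'
#' Maximum true stress on the curve. Post-yield data are expected to have
#' been trimmed upstream, so for monotone curves this is the terminal stress.
#'
#' @param curve A [stress_stretch_curve()].
#' @return UTS in MPa, with the stretch at which it occurs as attribute
#'   `at_stretch`.
#' @export
ultimate_tensile_stress <- function(curve) {
  if (nrow(curve) == 0L) abort("Empty curve.")
  i <- which.max(curve$stress_MPa)
  structure(curve$stress_MPa[[i]], at_stretch = curve$stretch[[i]])
}

#' Low- and high-stretch elastic moduli
#'
#' The low-stretch (toe-region) modulus is evaluated over `low_window`
#' (default \eqn{\lambda \in [1.00, 1.10]}); the high-stretch modulus over
#' the terminal fraction (`high_fraction`, default 10%) of the available
#' stretch range ending at the UTS point. Strain-stiffening materials give
#' `e_high > e_low`.
#'
#' @inheritParams elastic_modulus
#' @param low_window Stretch window for the toe modulus.
#' @param high_fraction Fraction of the stretch range (up to the UTS point)
#'   forming the terminal window.
#' @return Named list with `e_low`, `e_high` (MPa) and the two windows.
#' @export
low_high_moduli <- function(curve, low_window = c(1.0, 1.1), high_fraction = 0.1) {
  stopifnot(high_fraction > 0, high_fraction <= 1)
  uts <- ultimate_tensile_stress(curve)
  # anchor the terminal window at the *last* stretch attaining the maximum,
  # so plateaued (e.g. constant) curves keep a non-degenerate window
  lam_uts <- max(curve$stretch[curve$stress_MPa >= as.numeric(uts)])
  lam_min <- min(curve$stretch)
  if (lam_uts <= lam_min) {
    abort("Curve has no stretch range below its maximum-stress point.")
  }
  high_window <- c(lam_uts - high_fraction * (lam_uts - lam_min), lam_uts)
  list(
    e_low = elastic_modulus(curve, low_window),
    e_high = elastic_modulus(curve, high_window),
    low_window = low_window, high_window = high_window
  )
}

#' Linear-regime tissue metrics of a stress-stretch curve
#'
#' One-row summary of the descriptors used to compare surrogates with native
#' tissue: elastic modulus at low and high stretch and ultimate tensile
#' stress, each in MPa, together with the windows used (metric outputs always
#' carry their windows).
#'
#' @inheritParams low_high_moduli
#' @param label Specimen label carried into the output row.
#' @return A one-row tibble: `label`, `e_low_MPa`, `e_high_MPa`, `uts_MPa`,
#'   `window_low_lo`, `window_low_hi`, `window_high_lo`, `window_high_hi`.
#' @examples
#' tissue_metrics(generate_clean_curve(13.1, 0.21))
#' @export
tissue_metrics <- function(curve, low_window = c(1.0, 1.1), high_fraction = 0.1,
                           label = "") {
  m <- low_high_moduli(curve, low_window, high_fraction)
  uts <- ultimate_tensile_stress(curve)
  tibble(
    label = label,
    e_low_MPa = m$e_low, e_high_MPa = m$e_high, uts_MPa = as.numeric(uts),
    window_low_lo = m$low_window[[1]], window_low_hi = m$low_window[[2]],
    window_high_lo = m$high_window[[1]], window_high_hi = m$high_window[[2]]
  )
}

#' Repeatability summary of a metrics batch
#'
#' Per-metric mean and sample standard deviation (n-1 denominator; 0 for a
#' single specimen) across a batch of specimens, with the conventional
#' "mean +/- sd" presentation.
#'
#' @param metrics A tibble of per-specimen rows as returned by
#'   [tissue_metrics()] (rows may be bound together).
#' @return A tibble with one row per metric: `metric`, `n`, `mean`, `sd`,
#'   `formatted`.
#' @examples
#' batch <- dplyr::bind_rows(
#'   tissue_metrics(generate_clean_curve(13.1, 0.21)),
#'   tissue_metrics(generate_clean_curve(14.4, 0.27))
#' )
#' summarize_repeatability(batch)
#' @export
summarize_repeatability <- function(metrics) {
  if (!is.data.frame(metrics) || nrow(metrics) == 0L) {
    abort("`metrics` must be a non-empty data frame of per-specimen metrics.")
  }
  cols <- intersect(c("e_low_MPa", "e_high_MPa", "uts_MPa"), names(metrics))
  if (length(cols) == 0L) abort("`metrics` has no metric columns.")
  metrics |>
    select(dplyr::all_of(cols)) |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "metric") |>
    group_by(.data$metric) |>
    summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      sd = if (dplyr::n() < 2L) 0 else sd(.data$value),
      .groups = "drop"
    ) |>
    mutate(formatted = sprintf("%.3f ± %.3f", .data$mean, .data$sd)) |>
    arrange(match(.data$metric, cols))
}
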