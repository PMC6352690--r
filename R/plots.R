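# Convenience figures; never part of the tested numerical contract.

#' Plot a raw load-extension record
#'
#' @param object A [uniaxial_record()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot uniaxial_record
#' @export
autoplot.uniaxial_record <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$extension_mm, y = .data$load_N)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::labs(x = "Extension (mm)", y = "Load (N)",
                  title = attr(object, "label")) +
    ggplot2::theme_minimal()
}

#' Plot a stress-stretch curve
#'
#' @param object A [stress_stretch_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot stress_stretch_curve
#' @export
autoplot.stress_stretch_curve <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$stretch, y = .data$stress_MPa)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(x = expression(lambda), y = "True stress (MPa)") +
    ggplot2::theme_minimal()
}

#' Plot a Veronda-Westmann fit over its data
#'
#' @param object A `vw_fit`.
#' @param ... Unused.
#' @return A ggplot with observed points and the fitted stress law.
#' @method autoplot vw_fit
#' @export
autoplot.vw_fit <- function(object, ...) {
  dat <- object$data
  grid <- seq(min(dat$stretch), max(dat$stretch), length.out = 200)
  fitted <- tibble(stretch = grid,
                   stress_MPa = vw_uniaxial_stress(grid, object$c1, object$c2))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$stretch, y = .data$stress_MPa)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_line(data = fitted, colour = "firebrick", linewidth = 0.8) +
    ggplot2::labs(
      x = expression(lambda), y = "True stress (MPa)",
      subtitle = sprintf("c1 = %.3g MPa, c2 = %.3g, R² = %.4f",
                         object$c1, object$c2, object$r_squared)
    ) +
    ggplot2::theme_minimal()
}

#' Plot every catalog site's predicted curve
#'
#' @param grid Stretch grid.
#' @return A ggplot of the 11 per-site stress-stretch curves.
#' @export
plot_site_catalog <- function(grid = standard_stretch_grid()) {
  sites <- site_catalog()
  dat <- purrr::pmap(
    list(sites$sample_location, sites$c1_MPa, sites$c2),
    function(loc, c1, c2) {
      tibble(sample_location = factor(loc), stretch = grid,
             stress_MPa = vw_uniaxial_stress(grid, c1, c2))
    }
  ) |> list_rbind()
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$stretch, y = .data$stress_MPa,
                                    colour = .data$sample_location)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(lambda), y = "True stress (MPa)",
                  colour = "Site") +
    ggplot2::theme_minimal()
}
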