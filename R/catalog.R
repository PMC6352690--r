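# Bundled catalog files and their integrity checksums. The four weight
# percentages of every row sum to 100 (a four-part elastomer recipe).
.catalog_files <- list(
  compositions = list(file = "surrogate_compositions.csv",
                      md5 = "af8bdef7e0fb9e46ece5f394ecf4287e"),
  sites = list(file = "surrogate_sites.csv",
               md5 = "7919d718fc149e5338f23cd24fc48222")
)

load_catalog_file <- function(which) {
  info <- .catalog_files[[which]]
  path <- system.file("extdata", info$file, package = "vwskin", mustWork = TRUE)
  sum <- unname(tools::md5sum(path))
  if (!identical(sum, info$md5)) {
    abort(sprintf("Bundled catalog file `%s` failed its integrity check.", info$file))
  }
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Surrogate composition catalog
#'
#' The 23 four-part elastomer composition batches tested during surrogate
#' development. Each row gives the weight percentages of parts A and B of the
#' soft (Shore 00-10) and stiff (Shore 30A) two-part elastomers; the four
#' entries of every row total 100 wt %. The bundled file is checksum-guarded.
#'
#' @return A 23-row tibble: `specimen`, `shore0010_partA`, `shore0010_partB`,
#'   `shore30A_partA`, `shore30A_partB`.
#' @examples
#' composition_catalog()
#' @export
composition_catalog <- function() {
  out <- load_catalog_file("compositions")
  stopifnot(nrow(out) == 23L)
  out
}

#' Per-body-site surrogate catalog
#'
#' The 11 surrogate compositions that mimic human skin at different body
#' locations (back regions at several orientations to the Langer lines),
#' with their fitted Veronda-Westmann constants. `c1_MPa` carries stress
#' units by consistency with the reported stresses; `c2` is dimensionless.
#'
#' @return An 11-row tibble: `sample_location` (1-11), the four composition
#'   weight percentages, `c1_MPa`, `c2`.
#' @examples
#' site_catalog()
#' @export
site_catalog <- function() {
  out <- load_catalog_file("sites")
  stopifnot(nrow(out) == 11L)
  out
}

#' Predicted stress-stretch curve for a catalog site
#'
#' Forward-evaluates the uniaxial Veronda-Westmann stress law with the
#' site's catalog constants.
#'
#' @param sample_location Integer 1-11.
#' @param grid Stretch grid (default the standard 101-point grid).
#' @return A [stress_stretch_curve()].
#' @examples
#' predict_site_curve(6)[c(1, 51, 101), ]
#' @export
predict_site_curve <- function(sample_location, grid = standard_stretch_grid()) {
  loc <- sample_location
  sites <- site_catalog()
  row <- sites |> filter(.data$sample_location == loc)
  if (nrow(row) != 1L) {
    abort(sprintf("Unknown sample location %s; catalog covers 1-11.",
                  format(sample_location)))
  }
  generate_clean_curve(row$c1_MPa, row$c2, grid)
}

#' Match a measured curve against the site catalog
#'
#' Ranks the 11 catalog sites by root-mean-square deviation between the
#' target curve and each site's predicted curve, evaluated on the target's
#' own grid points inside the catalog's stretch range `[1, 2]`. Ties are
#' broken deterministically by sample location.
#'
#' @param target A [stress_stretch_curve()] with at least one grid point in
#'   `[1, 2]`.
#' @return A tibble sorted by ascending `rmse_MPa`: `sample_location`,
#'   `c1_MPa`, `c2`, `rmse_MPa`, `n_common`.
#' @examples
#' match_composition(predict_site_curve(3))
#' @export
match_composition <- function(target) {
  if (!all(c("stretch", "stress_MPa") %in% names(target))) {
    abort("`target` must have columns `stretch` and `stress_MPa`.")
  }
  sel <- target$stretch >= 1 & target$stretch <= 2
  if (!any(sel)) {
    abort("Target grid has no overlap with the catalog stretch range [1, 2].")
  }
  lam <- target$stretch[sel]
  obs <- target$stress_MPa[sel]
  sites <- site_catalog()
  sites |>
    mutate(
      rmse_MPa = map_dbl(seq_len(nrow(sites)), function(i) {
        pred <- vw_uniaxial_stress(lam, sites$c1_MPa[[i]], sites$c2[[i]])
        sqrt(mean((obs - pred)^2))
      }),
      n_common = length(lam)
    ) |>
    select("sample_location", "c1_MPa", "c2", "rmse_MPa", "n_common") |>
    arrange(.data$rmse_MPa, .data$sample_location)
}
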