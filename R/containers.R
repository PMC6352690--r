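#' Specimen geometry
#'
#' Geometry of a clamped tension coupon. Defaults match the standard test
#' coupon used throughout: 35 mm gauge length, 10 mm width, 3 mm thickness
#' (dimensions after clamping). The rectangular cross-section area is derived.
#'
#' @param gauge_length_mm Free length between grips, mm.
#' @param width_mm Coupon width, mm.
#' @param thickness_mm Coupon thickness, mm.
#'
#' @return An object of class `specimen_geometry`: a list with the three
#'   dimensions plus `area_mm2 = width_mm * thickness_mm`.
#' @examples
#' specimen_geometry()
#' @export
specimen_geometry <- function(gauge_length_mm = 35, width_mm = 10, thickness_mm = 3) {
  check_positive(gauge_length_mm, "gauge_length_mm")
  check_positive(width_mm, "width_mm")
  check_positive(thickness_mm, "thickness_mm")
  structure(
    list(
      gauge_length_mm = gauge_length_mm,
      width_mm = width_mm,
      thickness_mm = thickness_mm,
      area_mm2 = width_mm * thickness_mm
    ),
    class = "specimen_geometry"
  )
}

#' @export
print.specimen_geometry <- function(x, ...) {
  cat(sprintf(
    "<specimen_geometry> gauge %g mm, width %g mm, thickness %g mm (area %g mm^2)\n",
    x$gauge_length_mm, x$width_mm, x$thickness_mm, x$area_mm2
  ))
  invisible(x)
}

#' Raw uniaxial tension record
#'
#' A time-ordered load-extension record from one coupon test, as exported by
#' a universal testing machine, together with the specimen geometry. The
#' strain rate is stored verbatim as a string (it annotates the test
#' condition and is never computed with).
#'
#' @param extension_mm Numeric vector of crosshead extensions (mm),
#'   non-decreasing.
#' @param load_N Numeric vector of loads (N), same length.
#' @param geometry A [specimen_geometry()].
#' @param strain_rate Free-text test strain rate annotation.
#' @param label Free-text specimen label.
#'
#' @return A tibble of class `uniaxial_record` with columns `extension_mm`
#'   and `load_N`; geometry and metadata are carried as attributes.
#' @examples
#' uniaxial_record(c(0, 1, 2), c(0, 2, 5), specimen_geometry())
#' @export
uniaxial_record <- function(extension_mm, load_N, geometry = specimen_geometry(),
                            strain_rate = "0.4 s^-1", label = "") {
  if (length(extension_mm) != length(load_N)) {
    abort("`extension_mm` and `load_N` must have the same length.")
  }
  if (length(extension_mm) < 1L) {
    abort("A record needs at least one sample.")
  }
  if (any(!is.finite(extension_mm)) || any(!is.finite(load_N))) {
    abort("Extensions and loads must be finite.")
  }
  if (is.unsorted(extension_mm)) {
    abort("`extension_mm` must be non-decreasing (time-ordered test).")
  }
  stopifnot(inherits(geometry, "specimen_geometry"))
  out <- tibble(extension_mm = as.numeric(extension_mm), load_N = as.numeric(load_N))
  new_tibble(
    out,
    geometry = geometry,
    strain_rate = as.character(strain_rate),
    label = as.character(label),
    trim_log = empty_trim_log(),
    class = "uniaxial_record"
  )
}

empty_trim_log <- function() {
  tibble(step = character(), operation = character(), n_removed = integer(),
         note = character())
}

append_trim_log <- function(record, step, operation, n_removed, note = "") {
  log <- attr(record, "trim_log") %||% empty_trim_log()
  attr(record, "trim_log") <- bind_rows(
    log,
    tibble(step = step, operation = operation,
           n_removed = as.integer(n_removed), note = note)
  )
  record
}

# Rebuild a uniaxial_record around new columns, preserving metadata.
record_with <- function(record, extension_mm, load_N) {
  out <- new_tibble(
    tibble(extension_mm = extension_mm, load_N = load_N),
    geometry = attr(record, "geometry"),
    strain_rate = attr(record, "strain_rate"),
    label = attr(record, "label"),
    trim_log = attr(record, "trim_log") %||% empty_trim_log(),
    class = "uniaxial_record"
  )
  out
}

#' Processing log of a record or curve
#'
#' @param x A `uniaxial_record` or `stress_stretch_curve` produced by the
#'   preprocessing steps.
#' @return A tibble with one row per applied protocol step (`step`,
#'   `operation`, `n_removed`, `note`).
#' @export
processing_log <- function(x) {
  attr(x, "trim_log") %||% attr(x, "log") %||% empty_trim_log()
}

#' Stress-strain curve
#'
#' Paired strain/stress arrays. `kind` records the stress measure
#' (engineering = load over original area; true = Cauchy), `strain_kind` the
#' strain measure (engineering = extension over gauge length; true =
#' logarithmic). After trend resampling the two can legitimately differ: true
#' stress tabulated on a standardized engineering-strain grid.
#'
#' @param strain Dimensionless strain array.
#' @param stress_MPa Stress array, MPa.
#' @param kind `"engineering"` or `"true"` (stress measure).
#' @param strain_kind Strain measure; defaults to `kind`.
#'
#' @return A tibble of class `stress_strain_curve`.
#' @export
stress_strain_curve <- function(strain, stress_MPa,
                                kind = c("engineering", "true"),
                                strain_kind = NULL) {
  kind <- arg_match(kind)
  strain_kind <- strain_kind %||% kind
  strain_kind <- arg_match(strain_kind, c("engineering", "true"))
  if (length(strain) != length(stress_MPa)) {
    abort("`strain` and `stress_MPa` must have the same length.")
  }
  new_tibble(
    tibble(strain = as.numeric(strain), stress_MPa = as.numeric(stress_MPa)),
    kind = kind, strain_kind = strain_kind,
    class = "stress_strain_curve"
  )
}

#' Stress-stretch curve
#'
#' The pipeline's canonical end product: true stress tabulated on a stretch
#' grid (by default 101 points, 1.00 to 2.00 in steps of 0.01).
#'
#' @param stretch Dimensionless stretch array, all `> 0`.
#' @param stress_MPa True stress array, MPa.
#' @return A tibble of class `stress_stretch_curve`.
#' @examples
#' stress_stretch_curve(c(1, 1.5, 2), c(0, 6.9, 24.5))
#' @export
stress_stretch_curve <- function(stretch, stress_MPa) {
  if (length(stretch) != length(stress_MPa)) {
    abort("`stretch` and `stress_MPa` must have the same length.")
  }
  check_positive(stretch, "stretch")
  if (any(!is.finite(stress_MPa))) abort("`stress_MPa` must be finite.")
  new_tibble(
    tibble(stretch = as.numeric(stretch), stress_MPa = as.numeric(stress_MPa)),
    class = "stress_stretch_curve"
  )
}

#' Standard stretch grid
#'
#' The standardized abscissa used after trend resampling. Bit-for-bit
#' reproducible from `(start, stop, step)`.
#'
#' @param start,stop,step Grid limits and increment (stretch units).
#' @return Numeric vector; defaults give 101 points on `[1, 2]`.
#' @examples
#' length(standard_stretch_grid())
#' @export
standard_stretch_grid <- function(start = 1.0, stop = 2.0, step = 0.01) {
  if (step <= 0 || stop <= start) abort("Need `step > 0` and `stop > start`.")
  seq(start, stop, by = step)
}
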