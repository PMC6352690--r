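#' Specification for a synthetic raw tension record
#'
#' Parameters of the synthetic load-extension generator. The defaults
#' emulate the study conditions the pipeline was designed for: the control
#' surrogate's ground-truth constants (c1 = 13.1 MPa, c2 = 0.21), the
#' standard 35 x 10 x 3 mm clamped coupon, loading to stretch 2, a 0.5 mm
#' initial slack segment with slightly negative load-cell readings, 3%
#' multiplicative load noise, and a short geometric post-yield tail.
#'
#' @param c1,c2 Ground-truth Veronda-Westmann constants (MPa, dimensionless).
#' @param geometry A [specimen_geometry()].
#' @param stretch_max Final axial stretch of the loading branch (> 1).
#' @param n_points Samples on the loading branch, stretch 1 to `stretch_max`
#'   inclusive (the stretch-1 sample carries exactly zero load and marks the
#'   tension origin).
#' @param n_slack_points Samples in the slack segment (0 disables slack).
#' @param slack_extension_mm Crosshead travel consumed by slack.
#' @param slack_load_noise_N Scale of the negative half-normal load readings
#'   in the slack segment; must be `> 0` whenever slack is enabled (an
#'   exactly-zero slack shelf would be indistinguishable from the tension
#'   origin).
#' @param noise_cv Coefficient of variation of multiplicative Gaussian load
#'   noise on the loading branch (0 disables noise).
#' @param post_yield_fraction Per-sample geometric load-decay fraction of the
#'   rupture tail.
#' @param post_yield_points Samples in the rupture tail (0 disables it).
#' @param seed Integer RNG seed; spec + seed fully determine the record.
#' @return A validated list of class `synthetic_spec`.
#' @examples
#' synthetic_spec(seed = 42)
#' @export
synthetic_spec <- function(c1 = 13.1, c2 = 0.21,
                           geometry = specimen_geometry(),
                           stretch_max = 2.0, n_points = 300L,
                           n_slack_points = 20L, slack_extension_mm = 0.5,
                           slack_load_noise_N = 0.02,
                           noise_cv = 0.03,
                           post_yield_fraction = 0.15, post_yield_points = 10L,
                           seed = 1L) {
  spec <- list(
    c1 = c1, c2 = c2, geometry = geometry, stretch_max = stretch_max,
    n_points = as.integer(n_points), n_slack_points = as.integer(n_slack_points),
    slack_extension_mm = slack_extension_mm,
    slack_load_noise_N = slack_load_noise_N, noise_cv = noise_cv,
    post_yield_fraction = post_yield_fraction,
    post_yield_points = as.integer(post_yield_points), seed = as.integer(seed)
  )
  problems <- character()
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(is.numeric(c1) && c1 > 0, "`c1` must be > 0")
  chk(is.numeric(c2) && c2 > 0, "`c2` must be > 0")
  chk(inherits(geometry, "specimen_geometry"), "`geometry` must be a specimen_geometry")
  chk(is.numeric(stretch_max) && stretch_max > 1, "`stretch_max` must be > 1")
  chk(spec$n_points >= 2L, "`n_points` must be >= 2")
  chk(spec$n_slack_points >= 0L, "`n_slack_points` must be >= 0")
  chk(slack_extension_mm >= 0, "`slack_extension_mm` must be >= 0")
  chk(noise_cv >= 0, "`noise_cv` must be >= 0")
  chk(post_yield_fraction > 0 && post_yield_fraction < 1,
      "`post_yield_fraction` must be in (0, 1)")
  chk(spec$post_yield_points >= 0L, "`post_yield_points` must be >= 0")
  chk(!(spec$n_slack_points > 0L && spec$slack_extension_mm > 0 &&
          slack_load_noise_N <= 0),
      "`slack_load_noise_N` must be > 0 when the slack segment is enabled")
  if (length(problems) > 0L) {
    abort(paste0("Invalid synthetic spec:\n", paste("-", problems, collapse = "\n")))
  }
  structure(spec, class = "synthetic_spec")
}

#' Noise-free model curve on a grid
#'
#' Forward evaluation of the uniaxial true-stress law — the generating truth
#' that preprocessing and fitting are expected to recover.
#'
#' @inheritParams vw_energy
#' @param grid Stretch grid (default the standard 101-point grid).
#' @return A [stress_stretch_curve()].
#' @examples
#' generate_clean_curve(13.1, 0.21)[101, ]
#' @export
generate_clean_curve <- function(c1, c2, grid = standard_stretch_grid()) {
  stress_stretch_curve(grid, vw_uniaxial_stress(grid, c1, c2))
}

#' Generate one synthetic raw load-extension record
#'
#' Concatenates three segments: (a) a slack segment over
#' `[0, slack_extension_mm)` whose loads are negative half-normal readings
#' (a slack coupon carries no tension; the load cell reads slightly below
#' zero); (b) a loading branch mapping stretch `[1, stretch_max]` to
#' extension via `(lambda - 1) * gauge_length`, with engineering loads
#' `sigma_true(lambda) / lambda * area` perturbed by multiplicative Gaussian
#' noise; (c) a rupture tail whose load decays geometrically from the peak.
#' The record is bit-identical for identical spec + seed.
#'
#' @param spec A [synthetic_spec()].
#' @return A [uniaxial_record()]; the generating spec is attached as
#'   attribute `spec`.
#' @examples
#' rec <- synth_raw_record(synthetic_spec(seed = 7))
#' nrow(rec)
#' @export
synth_raw_record <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  geom <- spec$geometry
  withr::with_seed(spec$seed, {
    # (a) slack segment, strictly before the tension origin
    if (spec$n_slack_points > 0L && spec$slack_extension_mm > 0) {
      ext_slack <- seq(0, spec$slack_extension_mm,
                       length.out = spec$n_slack_points + 1L)[seq_len(spec$n_slack_points)]
      load_slack <- -abs(rnorm(spec$n_slack_points, 0, spec$slack_load_noise_N))
    } else {
      ext_slack <- numeric()
      load_slack <- numeric()
    }
    # (b) loading branch, stretch 1 (zero load, the origin) to stretch_max
    lam <- seq(1, spec$stretch_max, length.out = spec$n_points)
    ext_load <- spec$slack_extension_mm * (spec$n_slack_points > 0L) +
      (lam - 1) * geom$gauge_length_mm
    sigma_eng <- vw_uniaxial_stress(lam, spec$c1, spec$c2) / lam
    load_load <- sigma_eng * geom$area_mm2
    if (spec$noise_cv > 0) {
      load_load <- load_load * (1 + spec$noise_cv * rnorm(spec$n_points))
    }
    # (c) post-yield tail: geometric decay continuing at the last spacing
    if (spec$post_yield_points > 0L) {
      dx <- diff(tail(ext_load, 2))
      ext_tail <- tail(ext_load, 1) + dx * seq_len(spec$post_yield_points)
      load_tail <- tail(load_load, 1) *
        (1 - spec$post_yield_fraction)^seq_len(spec$post_yield_points)
    } else {
      ext_tail <- numeric()
      load_tail <- numeric()
    }
    rec <- uniaxial_record(
      extension_mm = c(ext_slack, ext_load, ext_tail),
      load_N = c(load_slack, load_load, load_tail),
      geometry = geom,
      label = sprintf("synthetic c1=%g c2=%g seed=%d", spec$c1, spec$c2, spec$seed)
    )
    attr(rec, "spec") <- spec
    rec
  })
}

#' Generate a repeatability batch of synthetic records
#'
#' Independent records with seeds `base_seed + 0, 1, ...`. Optional geometry
#' jitter draws width and thickness uniformly within the printed coupon
#' manufacturing tolerances (9-11 mm width, 2.8-3.1 mm thickness).
#'
#' @param spec A [synthetic_spec()] used as the template.
#' @param n_specimens Number of records (>= 1).
#' @param base_seed First seed; record `i` uses `base_seed + i - 1`.
#' @param geometry_jitter Draw per-specimen width/thickness within tolerance?
#' @return A list of [uniaxial_record()]s.
#' @examples
#' batch <- synth_repeatability_batch(synthetic_spec(), n_specimens = 3)
#' length(batch)
#' @export
synth_repeatability_batch <- function(spec, n_specimens, base_seed = spec$seed,
                                      geometry_jitter = FALSE) {
  stopifnot(inherits(spec, "synthetic_spec"), n_specimens >= 1L)
  map(seq_len(n_specimens), function(i) {
    seed_i <- as.integer(base_seed + i - 1L)
    geom <- spec$geometry
    if (geometry_jitter) {
      geom <- withr::with_seed(seed_i, specimen_geometry(
        gauge_length_mm = spec$geometry$gauge_length_mm,
        width_mm = runif(1, 9, 11),
        thickness_mm = runif(1, 2.8, 3.1)
      ))
    }
    spec_i <- synthetic_spec(
      c1 = spec$c1, c2 = spec$c2, geometry = geom,
      stretch_max = spec$stretch_max, n_points = spec$n_points,
      n_slack_points = spec$n_slack_points,
      slack_extension_mm = spec$slack_extension_mm,
      slack_load_noise_N = spec$slack_load_noise_N,
      noise_cv = spec$noise_cv,
      post_yield_fraction = spec$post_yield_fraction,
      post_yield_points = spec$post_yield_points,
      seed = seed_i
    )
    synth_raw_record(spec_i)
  })
}
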