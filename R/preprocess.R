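#' Pipeline configuration
#'
#' Settings for [preprocess_pipeline()]. Keys mirror the plain-text config
#' format accepted by the batch runners.
#'
#' @param poly_degree Trendline polynomial degree (default 5).
#' @param grid_start,grid_stop,grid_step Standardized stretch grid (defaults
#'   1.00 to 2.00 by 0.01, i.e. 101 points).
#' @param stretch_mode `"engineering_strain"` (default; uses the exact
#'   kinematic identity \eqn{\lambda = 1 + \varepsilon_{eng} =
#'   e^{\varepsilon_{true}}}) or `"paper_literal"` (applies
#'   \eqn{\lambda = 1 + \varepsilon} to whichever strain array is present).
#' @param r2_warn_threshold Trendline quality band: a warning (never an
#'   error) is raised when the trend R-squared falls below it.
#' @return A list of class `pipeline_config`.
#' @examples
#' pipeline_config()
#' @export
pipeline_config <- function(poly_degree = 5L,
                            grid_start = 1.0, grid_stop = 2.0, grid_step = 0.01,
                            stretch_mode = c("engineering_strain", "paper_literal"),
                            r2_warn_threshold = 0.95) {
  stretch_mode <- arg_match(stretch_mode)
  stopifnot(poly_degree >= 1, grid_step > 0, grid_stop > grid_start,
            r2_warn_threshold >= 0, r2_warn_threshold <= 1)
  structure(
    list(poly_degree = as.integer(poly_degree),
         grid_start = grid_start, grid_stop = grid_stop, grid_step = grid_step,
         stretch_mode = stretch_mode, r2_warn_threshold = r2_warn_threshold),
    class = "pipeline_config"
  )
}

# Index of the first sample opening a sustained run of strictly positive
# loads (run length >= min_run or reaching the end of the record); NA if the
# record never sustains tension.
first_sustained_positive <- function(load, min_run = 5L) {
  n <- length(load)
  pos <- load > 0
  run <- 0L
  # suffix run lengths of consecutive positives
  runs <- integer(n)
  for (i in rev(seq_len(n))) {
    run <- if (pos[i]) run + 1L else 0L
    runs[i] <- run
  }
  idx <- which(pos & (runs >= min_run | (seq_len(n) + runs - 1L) == n))
  if (length(idx) == 0L) NA_integer_ else idx[[1]]
}

#' Step (i): trim the initial slack region
#'
#' Machine records of soft coupons often open with a slack segment of
#' near-zero or negative loads before the specimen takes tension. This step
#' removes every sample up to and including the last strictly negative load
#' that precedes the first sustained run of positive loads; a genuinely zero
#' load at the tension onset is kept, since it marks the origin. Negative
#' loads occurring *after* tension is established indicate grip failure and
#' abort with a data-quality error rather than being trimmed silently.
#'
#' @param record A [uniaxial_record()].
#' @param min_run Minimum length of a load run counted as sustained tension.
#' @return The trimmed record; the number of removed samples is appended to
#'   its [processing_log()].
#' @export
trim_negative_loads <- function(record, min_run = 5L) {
  load <- record$load_N
  s <- first_sustained_positive(load, min_run)
  if (is.na(s)) {
    abort("All loads are non-positive: record is entirely slack (empty curve).")
  }
  neg_before <- which(load < 0 & seq_along(load) < s)
  g <- if (length(neg_before)) max(neg_before) else 0L
  if (any(load[seq(s, length(load))] < 0)) {
    abort("Negative load after sustained tension onset: possible grip failure.")
  }
  keep <- seq_along(load) > g
  out <- record_with(record, record$extension_mm[keep], record$load_N[keep])
  append_trim_log(out, "i", "trim_negative_loads", sum(!keep))
}

#' Step (ii): truncate after the yield point
#'
#' The yield point is taken as the global load maximum (earliest index on a
#' plateau); everything after it — the rupture/post-yield tail — is removed.
#'
#' @param record A [uniaxial_record()].
#' @return The truncated record, with the removal count logged.
#' @export
trim_post_yield <- function(record) {
  i_max <- which.max(record$load_N)
  keep <- seq_len(i_max)
  out <- record_with(record, record$extension_mm[keep], record$load_N[keep])
  append_trim_log(out, "ii", "trim_post_yield", nrow(record) - i_max)
}

#' Step (iii): shift the record to start at the origin
#'
#' Subtracts the first extension from all extensions and the first load from
#' all loads, so the retained curve starts at (0, 0). This implicitly removes
#' any small pre-load applied to take up slack.
#'
#' @param record A [uniaxial_record()] whose first load is `>= 0`.
#' @return The shifted record.
#' @export
shift_to_origin <- function(record) {
  if (record$load_N[[1]] < 0) {
    abort("First load is negative; run trim_negative_loads() first.")
  }
  out <- record_with(
    record,
    record$extension_mm - record$extension_mm[[1]],
    record$load_N - record$load_N[[1]]
  )
  append_trim_log(out, "iii", "shift_to_origin", 0L,
                  note = sprintf("shift (%.6g mm, %.6g N)",
                                 record$extension_mm[[1]], record$load_N[[1]]))
}

#' Step (iv a): engineering stress-strain from load-extension
#'
#' \eqn{\varepsilon_{eng} = \Delta L / L_0},
#' \eqn{\sigma_{eng} = F / A_0} with N/mm\eqn{^2} reported as MPa.
#'
#' @param record An origin-shifted [uniaxial_record()].
#' @return A [stress_strain_curve()] of kind `"engineering"`.
#' @export
to_engineering <- function(record) {
  geom <- attr(record, "geometry")
  if (is.null(geom) || geom$area_mm2 <= 0 || geom$gauge_length_mm <= 0) {
    abort("Record carries no valid specimen geometry.")
  }
  out <- stress_strain_curve(
    strain = record$extension_mm / geom$gauge_length_mm,
    stress_MPa = record$load_N / geom$area_mm2,
    kind = "engineering"
  )
  attr(out, "trim_log") <- attr(record, "trim_log")
  out
}

#' Step (iv b): engineering to true stress-strain
#'
#' \eqn{\sigma_{true} = \sigma_{eng}(1 + \varepsilon_{eng})} (incompressible
#' area change) and \eqn{\varepsilon_{true} = \ln(1 + \varepsilon_{eng})}.
#'
#' @param curve A [stress_strain_curve()] of kind `"engineering"`.
#' @return A [stress_strain_curve()] of kind `"true"`.
#' @export
eng_to_true <- function(curve) {
  if (!identical(attr(curve, "kind"), "engineering")) {
    abort("`eng_to_true()` expects an engineering stress-strain curve.")
  }
  if (any(curve$strain <= -1)) {
    abort("Engineering strain <= -1 is outside the log-strain domain.")
  }
  out <- stress_strain_curve(
    strain = log1p(curve$strain),
    stress_MPa = curve$stress_MPa * (1 + curve$strain),
    kind = "true"
  )
  attr(out, "trim_log") <- attr(curve, "trim_log")
  out
}

#' Step (v): fit a polynomial trendline
#'
#' Least-squares polynomial of true stress against strain. By default the
#' regression abscissa is engineering strain (\eqn{\lambda - 1}, recovered
#' exactly from log strain via \eqn{\varepsilon_{eng} = e^{\varepsilon_{true}}
#' - 1}), matching the standardized stretch axis on which the trend is later
#' resampled; set `x = "true"` to regress on log strain directly. A warning
#' is raised when the coefficient of determination falls below
#' `r2_warn_threshold`, mirroring the protocol's 0.95-1 quality band.
#'
#' @param curve A [stress_strain_curve()] (the pipeline passes the true
#'   stress-strain curve of step iv).
#' @param degree Polynomial degree, default 5.
#' @param x Regression abscissa: `"engineering"` (default) or `"true"`.
#' @param r2_warn_threshold Quality-band threshold for the warning.
#' @return An object of class `poly_trend`: coefficients (descending powers),
#'   `r_squared`, fitted `domain` in the regression variable, `x_kind`, `n`.
#' @export
fit_poly_trend <- function(curve, degree = 5L, x = c("engineering", "true"),
                           r2_warn_threshold = 0.95) {
  x <- arg_match(x)
  stopifnot(inherits(curve, "stress_strain_curve"))
  xs <- curve_strain_as(curve, x)
  ys <- curve$stress_MPa
  if (length(unique(xs)) < degree + 1L) {
    abort(sprintf(
      "Underdetermined fit: degree %d needs at least %d distinct strain values, got %d.",
      degree, degree + 1L, length(unique(xs))
    ))
  }
  fit <- lm(ys ~ stats::poly(xs, degree, raw = TRUE))
  beta <- coef(fit)
  beta[is.na(beta)] <- 0
  coefs <- rev(unname(beta)) # descending powers
  r2 <- r_squared(ys, stats::fitted(fit))
  if (r2 < r2_warn_threshold) {
    warn(sprintf("Trendline R^2 = %.4f is below the %.2f quality band.",
                 r2, r2_warn_threshold))
  }
  structure(
    list(coefficients = coefs, r_squared = r2,
         domain = range(xs), x_kind = x, degree = as.integer(degree),
         n = length(xs)),
    class = "poly_trend"
  )
}

# Strain array of `curve` expressed in the requested measure, using the exact
# bijection eps_eng = exp(eps_true) - 1.
curve_strain_as <- function(curve, measure) {
  have <- attr(curve, "strain_kind")
  if (identical(have, measure)) {
    curve$strain
  } else if (identical(have, "true") && identical(measure, "engineering")) {
    expm1(curve$strain)
  } else {
    log1p(curve$strain)
  }
}

#' Evaluate a polynomial trend
#'
#' @param object A `poly_trend`.
#' @param newdata Numeric vector of strain values (in the trend's `x_kind`).
#' @param ... Unused.
#' @return Numeric vector of predicted stresses (MPa). Evaluation outside the
#'   fitted domain is refused (extrapolation guard); use
#'   [resample_standard_grid()] for clipped evaluation.
#' @export
predict.poly_trend <- function(object, newdata, ...) {
  outside <- newdata < object$domain[[1]] - 1e-12 | newdata > object$domain[[2]] + 1e-12
  if (any(outside)) {
    abort(sprintf(
      "Trend evaluation outside fitted domain [%.4g, %.4g] is forbidden.",
      object$domain[[1]], object$domain[[2]]
    ))
  }
  # Horner evaluation of the descending-power coefficients
  pred <- rep(0, length(newdata))
  for (b in object$coefficients) pred <- pred * newdata + b
  pred
}

#' Step (vi): resample a trend on the standardized grid
#'
#' Evaluates the trendline on a standardized strain grid. Grid points outside
#' the fitted domain are clipped away with a warning — never silently
#' extrapolated.
#'
#' @param trend A `poly_trend` from [fit_poly_trend()].
#' @param grid Numeric strain grid in the trend's regression variable
#'   (engineering strain for the pipeline default, i.e. stretch minus 1).
#' @return A [stress_strain_curve()] with true stress on the grid (its
#'   `strain_kind` is the trend's `x_kind`).
#' @export
resample_standard_grid <- function(trend, grid) {
  stopifnot(inherits(trend, "poly_trend"))
  if (length(grid) == 0L) abort("`grid` must be non-empty.")
  inside <- grid >= trend$domain[[1]] - 1e-12 & grid <= trend$domain[[2]] + 1e-12
  if (!any(inside)) {
    abort("No grid point lies inside the trend's fitted domain.")
  }
  if (!all(inside)) {
    warn(sprintf(
      "Clipped %d grid point(s) outside the fitted strain domain [%.4g, %.4g].",
      sum(!inside), trend$domain[[1]], trend$domain[[2]]
    ))
  }
  g <- grid[inside]
  stress_strain_curve(
    strain = g, stress_MPa = predict(trend, g),
    kind = "true", strain_kind = trend$x_kind
  )
}

#' Step (vii): convert a strain axis to stretch
#'
#' Default mode `engineering_strain` applies the exact identity
#' \eqn{\lambda = 1 + \varepsilon_{eng} = e^{\varepsilon_{true}}}, converting
#' whichever strain measure the curve carries. Mode `paper_literal`
#' reproduces the protocol's literal arithmetic \eqn{\lambda = 1 +
#' \varepsilon} on the strain array as-is, whatever its measure.
#'
#' @param curve A [stress_strain_curve()].
#' @param mode `"engineering_strain"` (default) or `"paper_literal"`.
#' @return A [stress_stretch_curve()].
#' @export
to_stretch <- function(curve, mode = c("engineering_strain", "paper_literal")) {
  mode <- arg_match(mode)
  stopifnot(inherits(curve, "stress_strain_curve"))
  lambda <- switch(mode,
    engineering_strain = 1 + curve_strain_as(curve, "engineering"),
    paper_literal = 1 + curve$strain
  )
  out <- stress_stretch_curve(lambda, curve$stress_MPa)
  attr(out, "trim_log") <- attr(curve, "trim_log")
  out
}

#' Full seven-step preprocessing protocol
#'
#' Applies, in order: (i) slack trimming, (ii) yield truncation, (iii) origin
#' shift, (iv) engineering and true stress-strain conversion, (v) degree-5
#' polynomial trendline, (vi) resampling on the standardized stretch grid,
#' (vii) stretch conversion. Any stage error is re-raised tagged with its
#' protocol step.
#'
#' @param record A [uniaxial_record()] with at least 2 samples.
#' @param config A [pipeline_config()].
#' @return A [stress_stretch_curve()] carrying attributes `log` (per-step
#'   trim counts, see [processing_log()]) and `trend` (the fitted
#'   `poly_trend`).
#' @examples
#' rec <- synth_raw_record(synthetic_spec(noise_cv = 0, seed = 1))
#' curve <- preprocess_pipeline(rec)
#' head(curve)
#' @export
preprocess_pipeline <- function(record, config = pipeline_config()) {
  stopifnot(inherits(record, "uniaxial_record"), inherits(config, "pipeline_config"))
  if (nrow(record) < 2L) abort("step (i): record needs at least 2 samples.")
  step <- function(id, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("step (%s): %s", id, conditionMessage(e)))
    })
  }
  rec <- step("i", trim_negative_loads(record))
  rec <- step("ii", trim_post_yield(rec))
  rec <- step("iii", shift_to_origin(rec))
  eng <- step("iv", to_engineering(rec))
  tru <- step("iv", eng_to_true(eng))
  trend <- step("v", fit_poly_trend(tru, degree = config$poly_degree,
                                    x = "engineering",
                                    r2_warn_threshold = config$r2_warn_threshold))
  grid <- standard_stretch_grid(config$grid_start, config$grid_stop, config$grid_step)
  resampled <- step("vi", resample_standard_grid(trend, grid - 1))
  out <- step("vii", to_stretch(resampled, mode = config$stretch_mode))
  attr(out, "log") <- attr(resampled, "trim_log") %||% attr(tru, "trim_log")
  attr(out, "trim_log") <- NULL
  attr(out, "trend") <- trend
  attr(out, "config") <- config
  out
}
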