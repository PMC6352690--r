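#' Coefficient of determination
#'
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}}. When the observations are constant
#' (\eqn{SS_{tot} = 0}) the value is defined as 0 with a warning: constant
#' data admit no explained variance. Values are clipped to `[0, 1]` unless
#' `clip = FALSE` (the raw value is what fit objects keep in diagnostics).
#'
#' @param observed,predicted Equal-length numeric vectors (length >= 2).
#' @param clip Clip the result into `[0, 1]`?
#' @return A single number.
#' @examples
#' r_squared(c(0, 1, 2), c(0, 1, 3))
#' @export
r_squared <- function(observed, predicted, clip = TRUE) {
  if (length(observed) != length(predicted)) {
    abort("`observed` and `predicted` must have the same length.")
  }
  if (length(observed) < 2L) abort("Need at least 2 points for R^2.")
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) {
    warn("Constant observations: R^2 defined as 0 (no explainable variance).")
    return(0)
  }
  r2 <- 1 - sum((observed - predicted)^2) / ss_tot
  if (clip) min(max(r2, 0), 1) else r2
}

# Profile closed form: the stress law is linear in c1, so for a fixed c2 the
# least-squares c1 is available in closed form. Used to seed multi-starts.
profile_c1 <- function(stretch, stress, c2, bounds_c1) {
  g <- vw_uniaxial_stress(stretch, c1 = 1, c2 = c2)
  denom <- sum(g^2)
  c1 <- if (denom > 0) sum(stress * g) / denom else bounds_c1[[1]]
  min(max(c1, bounds_c1[[1]]), bounds_c1[[2]])
}

#' Fit the Veronda-Westmann model to a stress-stretch curve
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt via
#' [minpack.lm::nlsLM()]) of the uniaxial true-stress law
#' [vw_uniaxial_stress()] to observed true stress, unweighted, in
#' stress-stretch space. On failure or non-convergence from the supplied
#' start, a deterministic multi-start fallback tries five log-spaced `c2`
#' values (each with its closed-form profiled `c1`) and keeps the best
#' residual sum of squares. A result that still has not converged is returned
#' flagged, with a warning — never silently.
#'
#' @param curve A [stress_stretch_curve()] (or data frame with `stretch` and
#'   `stress_MPa`), at least 3 points, stretches `> 0`.
#' @param init Named start values `c(c1 = , c2 = )`. The default (10, 0.25)
#'   sits near the middle of the catalog coefficient cloud.
#' @param bounds List with elements `c1` and `c2`, each `c(lower, upper)`.
#' @param max_iter Maximum Levenberg-Marquardt iterations.
#' @return An object of class `vw_fit` with elements `c1`, `c2`,
#'   `r_squared` (clipped), `r_squared_raw`, `residuals`, `fitted`,
#'   `n_points`, `converged`, `rss`, `init`, `bounds`, `data`.
#' @examples
#' curve <- generate_clean_curve(13.1, 0.21)
#' fit <- fit_veronda_westmann(curve)
#' tidy(fit)
#' @export
fit_veronda_westmann <- function(curve,
                                 init = c(c1 = 10, c2 = 0.25),
                                 bounds = list(c1 = c(1e-6, 1e3), c2 = c(1e-6, 10)),
                                 max_iter = 200L) {
  if (!all(c("stretch", "stress_MPa") %in% names(curve))) {
    abort("`curve` must have columns `stretch` and `stress_MPa`.")
  }
  stretch <- curve$stretch
  stress <- curve$stress_MPa
  if (length(stretch) < 3L) abort("Need at least 3 points to fit two constants.")
  check_positive(stretch, "stretch")
  if (all(stress == 0)) abort("Degenerate curve: all stresses are zero.")
  init <- c(c1 = unname(init[["c1"]]), c2 = unname(init[["c2"]]))

  dat <- data.frame(lam = stretch, sig = stress)
  ctrl <- minpack.lm::nls.lm.control(
    maxiter = as.integer(max_iter), ftol = 1e-14, ptol = 1e-14
  )
  one_fit <- function(start) {
    tryCatch({
      m <- minpack.lm::nlsLM(
        sig ~ vw_uniaxial_stress(lam, c1, c2),
        data = dat, start = as.list(start),
        lower = c(bounds$c1[[1]], bounds$c2[[1]]),
        upper = c(bounds$c1[[2]], bounds$c2[[2]]),
        control = ctrl
      )
      p <- coef(m)
      list(c1 = unname(p[["c1"]]), c2 = unname(p[["c2"]]),
           rss = sum(stats::residuals(m)^2),
           converged = m$convInfo$isConv %||% TRUE)
    }, error = function(e) NULL)
  }

  best <- one_fit(init)
  if (is.null(best) || !isTRUE(best$converged)) {
    # deterministic multi-start: log-spaced c2, profiled c1
    c2_starts <- 10^seq(log10(0.02), log10(2), length.out = 5)
    for (c2s in c2_starts) {
      cand <- one_fit(c(
        c1 = profile_c1(stretch, stress, c2s, bounds$c1), c2 = c2s
      ))
      if (!is.null(cand) && (is.null(best) || cand$rss < best$rss)) best <- cand
    }
  }
  if (is.null(best)) {
    abort("Veronda-Westmann fit failed from every start value.")
  }

  fitted <- vw_uniaxial_stress(stretch, best$c1, best$c2)
  res <- stress - fitted
  r2_raw <- suppressWarnings(r_squared(stress, fitted, clip = FALSE))
  out <- structure(
    list(
      c1 = best$c1, c2 = best$c2,
      r_squared = min(max(r2_raw, 0), 1), r_squared_raw = r2_raw,
      residuals = res, fitted = fitted,
      n_points = length(stretch), converged = isTRUE(best$converged),
      rss = sum(res^2), init = init, bounds = bounds,
      data = tibble(stretch = stretch, stress_MPa = stress)
    ),
    class = "vw_fit"
  )
  if (!out$converged) {
    warn("Veronda-Westmann fit did not converge; result returned flagged.")
  }
  out
}

#' @export
print.vw_fit <- function(x, ...) {
  cat(sprintf(
    "<vw_fit> c1 = %.4g MPa, c2 = %.4g (R^2 = %.4f, n = %d%s)\n",
    x$c1, x$c2, x$r_squared, x$n_points,
    if (x$converged) "" else ", NOT converged"
  ))
  invisible(x)
}

#' Tidy a Veronda-Westmann fit
#'
#' @param x A `vw_fit`.
#' @param ... Unused.
#' @return `tidy()`: one row per constant (`term`, `estimate`);
#'   `glance()`: one-row model summary.
#' @method tidy vw_fit
#' @export
tidy.vw_fit <- function(x, ...) {
  tibble(term = c("c1", "c2"), estimate = c(x$c1, x$c2),
         unit = c("MPa", "1"))
}

#' @rdname tidy.vw_fit
#' @method glance vw_fit
#' @export
glance.vw_fit <- function(x, ...) {
  tibble(c1 = x$c1, c2 = x$c2, r_squared = x$r_squared,
         r_squared_raw = x$r_squared_raw, rss = x$rss,
         n_points = x$n_points, converged = x$converged)
}

#' Fit a batch of curves and summarize the constants
#'
#' Fits each curve independently; per-curve errors are collected, not fatal.
#' The summary averages the *fitted parameters* across curves (never pooled
#' data) with sample standard deviations (n-1 denominator; 0 for a single
#' curve), excluding failed fits and reporting the exclusion count.
#'
#' @param curves A non-empty list of [stress_stretch_curve()]s.
#' @param ... Passed on to [fit_veronda_westmann()].
#' @return An object of class `vw_fit_batch`: list with `fits` (per-curve
#'   `vw_fit` or `NULL`), `results` (per-curve tibble with any `error`
#'   message), `summary` (one-row tibble), `n_excluded`.
#' @export
fit_batch <- function(curves, ...) {
  if (!is.list(curves) || length(curves) == 0L || inherits(curves, "data.frame")) {
    abort("`curves` must be a non-empty list of stress-stretch curves.")
  }
  fits <- map(curves, function(cv) {
    tryCatch(fit_veronda_westmann(cv, ...), error = function(e) e)
  })
  results <- imap(fits, function(f, i) {
    if (inherits(f, "error")) {
      tibble(curve = i, c1 = NA_real_, c2 = NA_real_, r_squared = NA_real_,
             converged = NA, error = conditionMessage(f))
    } else {
      tibble(curve = i, c1 = f$c1, c2 = f$c2, r_squared = f$r_squared,
             converged = f$converged, error = NA_character_)
    }
  }) |> list_rbind()
  ok <- results |> filter(is.na(.data$error))
  if (nrow(ok) == 0L) abort("Every curve in the batch failed to fit.")
  sd0 <- function(v) if (length(v) < 2L) 0 else sd(v)
  summary <- tibble(
    n_fitted = nrow(ok), n_excluded = nrow(results) - nrow(ok),
    mean_c1 = mean(ok$c1), sd_c1 = sd0(ok$c1),
    mean_c2 = mean(ok$c2), sd_c2 = sd0(ok$c2),
    mean_r_squared = mean(ok$r_squared), sd_r_squared = sd0(ok$r_squared)
  )
  structure(
    list(fits = map(fits, function(f) if (inherits(f, "error")) NULL else f),
         results = results, summary = summary,
         n_excluded = summary$n_excluded),
    class = "vw_fit_batch"
  )
}

#' @export
print.vw_fit_batch <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<vw_fit_batch> %d fitted (%d excluded): c1 = %.3g +/- %.3g MPa, c2 = %.3g +/- %.3g, mean R^2 = %.4f\n",
    s$n_fitted, s$n_excluded, s$mean_c1, s$sd_c1, s$mean_c2, s$sd_c2, s$mean_r_squared
  ))
  invisible(x)
}

#' @rdname tidy.vw_fit
#' @method tidy vw_fit_batch
#' @export
tidy.vw_fit_batch <- function(x, ...) x$results

#' @rdname tidy.vw_fit
#' @method glance vw_fit_batch
#' @export
glance.vw_fit_batch <- function(x, ...) x$summary
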