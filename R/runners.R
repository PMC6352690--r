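# Batch drivers: file-in/file-out orchestration of the pipeline stages.
# Each writes its resolved configuration next to its outputs so a saved run
# directory reproduces the run. Per-file failures are collected, not fatal.

#' Simulate a batch of raw records to disk
#'
#' @param out_dir Output directory (created if missing).
#' @param spec A [synthetic_spec()] template.
#' @param n_specimens Number of records.
#' @param base_seed First seed (record i uses `base_seed + i - 1`).
#' @param geometry_jitter Passed to [synth_repeatability_batch()].
#' @return A tibble with one row per written record (`file`, `seed`).
#' @export
run_simulate <- function(out_dir, spec = synthetic_spec(), n_specimens = 1L,
                         base_seed = spec$seed, geometry_jitter = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  batch <- synth_repeatability_batch(spec, n_specimens, base_seed, geometry_jitter)
  files <- imap(batch, function(rec, i) {
    f <- file.path(out_dir, sprintf("record_%03d.csv", i))
    write_uniaxial_record(rec, f)
    tibble(file = f, seed = as.integer(base_seed + i - 1L))
  }) |> list_rbind()
  write_keyvalue(
    list(c1 = spec$c1, c2 = spec$c2, stretch_max = spec$stretch_max,
         n_points = spec$n_points, n_slack_points = spec$n_slack_points,
         slack_extension_mm = spec$slack_extension_mm,
         slack_load_noise_N = spec$slack_load_noise_N,
         noise_cv = spec$noise_cv,
         post_yield_fraction = spec$post_yield_fraction,
         post_yield_points = spec$post_yield_points,
         base_seed = base_seed, n_specimens = n_specimens),
    file.path(out_dir, "simulate_config.txt")
  )
  files
}

#' Preprocess record files into standardized curve files
#'
#' @param inputs Character vector of record file paths.
#' @param out_dir Output directory.
#' @param config A [pipeline_config()]; written to `out_dir` as
#'   `preprocess_config.txt`.
#' @param geometry Optional [specimen_geometry()] override for all inputs.
#' @return A tibble with one row per input: `input`, `output`, `ok`,
#'   `n_trimmed_slack`, `n_trimmed_yield`, `trend_r2`, `error`.
#' @export
run_preprocess <- function(inputs, out_dir, config = pipeline_config(),
                           geometry = NULL) {
  if (length(inputs) == 0L) abort("No input record files given.")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_config(config, file.path(out_dir, "preprocess_config.txt"))
  rows <- map(inputs, function(path) {
    res <- tryCatch({
      rec <- read_uniaxial_record(path, geometry = geometry)
      curve <- preprocess_pipeline(rec, config)
      log <- processing_log(curve)
      out <- file.path(out_dir, paste0(
        tools::file_path_sans_ext(basename(path)), "_curve.csv"
      ))
      write_stress_stretch(curve, out)
      tibble(
        input = path, output = out, ok = TRUE,
        n_trimmed_slack = log$n_removed[log$step == "i"][1],
        n_trimmed_yield = log$n_removed[log$step == "ii"][1],
        trend_r2 = attr(curve, "trend")$r_squared,
        error = NA_character_
      )
    }, error = function(e) {
      tibble(input = path, output = NA_character_, ok = FALSE,
             n_trimmed_slack = NA_integer_, n_trimmed_yield = NA_integer_,
             trend_r2 = NA_real_, error = conditionMessage(e))
    })
    res
  })
  list_rbind(rows)
}

#' Fit curve files and write per-curve and summary reports
#'
#' @param inputs Character vector of curve file paths (pipeline output
#'   format).
#' @param out_dir Optional directory for `key = value` fit reports and a
#'   summary file.
#' @param ... Passed to [fit_veronda_westmann()].
#' @return The [fit_batch()] result, with a `files` tibble attached as an
#'   attribute when reports were written.
#' @export
run_fit <- function(inputs, out_dir = NULL, ...) {
  if (length(inputs) == 0L) abort("No input curve files given.")
  curves <- map(inputs, function(p) {
    tryCatch(read_stress_stretch(p), error = function(e) e)
  })
  unreadable <- map_dbl(curves, function(x) inherits(x, "error")) == 1
  batch <- fit_batch(curves[!unreadable], ...)
  batch$results$curve <- inputs[!unreadable][batch$results$curve]
  if (any(unreadable)) {
    batch$results <- bind_rows(
      batch$results,
      tibble(curve = inputs[unreadable], c1 = NA_real_, c2 = NA_real_,
             r_squared = NA_real_, converged = NA,
             error = vapply(curves[unreadable], conditionMessage, character(1)))
    )
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(batch$fits)) {
      if (is.null(batch$fits[[i]])) next
      nm <- tools::file_path_sans_ext(basename(inputs[!unreadable][i]))
      write_fit_report(batch$fits[[i]], file.path(out_dir, paste0(nm, "_fit.txt")))
    }
    readr::write_csv(batch$summary, file.path(out_dir, "fit_summary.csv"),
                     progress = FALSE)
  }
  batch
}

#' Compute tissue metrics for curve files
#'
#' @param inputs Character vector of curve file paths.
#' @param out_dir Optional directory for the delimited metrics report.
#' @param ... Passed to [tissue_metrics()].
#' @return A tibble with one row per readable curve plus, when more than one
#'   curve was processed, a repeatability summary attached as attribute
#'   `summary` (and a `summary` row block in the written report).
#' @export
run_metrics <- function(inputs, out_dir = NULL, ...) {
  if (length(inputs) == 0L) abort("No input curve files given.")
  rows <- map(inputs, function(p) {
    tryCatch(
      tissue_metrics(read_stress_stretch(p), label = basename(p), ...),
      error = function(e) tibble(label = basename(p), e_low_MPa = NA_real_,
                                 e_high_MPa = NA_real_, uts_MPa = NA_real_)
    )
  }) |> list_rbind()
  ok <- rows |> filter(!is.na(.data$e_low_MPa))
  summ <- if (nrow(ok) > 1L) summarize_repeatability(ok) else NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(rows, file.path(out_dir, "metrics.csv"), progress = FALSE)
    if (!is.null(summ)) {
      readr::write_csv(summ, file.path(out_dir, "metrics_summary.csv"),
                       progress = FALSE)
    }
  }
  attr(rows, "summary") <- summ
  rows
}
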