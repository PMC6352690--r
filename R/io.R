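# Plain-text interchange: delimited records/curves plus "key = value"
# sidecar metadata, the formats a testing-machine export workflow produces.

#' Read and write key = value metadata files
#'
#' One `key = value` pair per line; blank lines and `#` comments ignored.
#' Values that parse as numbers are returned numeric.
#'
#' @param path File path.
#' @return A named list.
#' @export
read_keyvalue <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([^=]+)=(.*)$", ln))[[1]]
    if (length(m) != 3L) abort(sprintf("Malformed key=value line: '%s'", ln))
    key <- trimws(m[[2]])
    val <- trimws(m[[3]])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num) && grepl("^[-+0-9.eE]+$", val)) num else val
  }
  out
}

#' @rdname read_keyvalue
#' @param x Named list (or flat named vector) to serialize.
#' @export
write_keyvalue <- function(x, path) {
  stopifnot(!is.null(names(x)), all(nzchar(names(x))))
  vals <- vapply(x, function(v) {
    if (is.numeric(v)) format(v, digits = 15) else as.character(v)
  }, character(1))
  readr::write_lines(paste(names(x), "=", vals), path)
  invisible(path)
}

#' Read a raw load-extension record from delimited text
#'
#' Accepts comma- or tab-delimited files with two mandatory columns
#' `extension_mm` and `load_N` (a header is optional: headerless files are
#' read positionally). Geometry comes from, in order of precedence, the
#' `geometry` argument, a `<path>.meta` sidecar with keys `gauge_length_mm`,
#' `width_mm`, `thickness_mm`, or the standard coupon default.
#'
#' @param path Delimited text file.
#' @param geometry Optional [specimen_geometry()] override.
#' @return A [uniaxial_record()].
#' @export
read_uniaxial_record <- function(path, geometry = NULL) {
  if (!file.exists(path)) abort(sprintf("No such input file: '%s'", path))
  first <- readr::read_lines(path, n_max = 1L, progress = FALSE)
  delim <- if (grepl("\t", first)) "\t" else ","
  has_header <- grepl("[A-Za-z]", first)
  tab <- readr::read_delim(
    path, delim = delim, col_names = has_header == TRUE,
    show_col_types = FALSE, progress = FALSE
  )
  if (!has_header) {
    if (ncol(tab) < 2L) abort("Headerless record file needs two columns.")
    names(tab)[1:2] <- c("extension_mm", "load_N")
  }
  if (!all(c("extension_mm", "load_N") %in% names(tab))) {
    abort(sprintf("'%s' must provide columns extension_mm and load_N.", path))
  }
  meta_path <- paste0(path, ".meta")
  meta <- if (file.exists(meta_path)) read_keyvalue(meta_path) else list()
  if (is.null(geometry)) {
    geometry <- specimen_geometry(
      gauge_length_mm = meta$gauge_length_mm %||% 35,
      width_mm = meta$width_mm %||% 10,
      thickness_mm = meta$thickness_mm %||% 3
    )
  }
  uniaxial_record(
    extension_mm = tab$extension_mm, load_N = tab$load_N,
    geometry = geometry,
    strain_rate = as.character(meta$strain_rate %||% "0.4 s^-1"),
    label = as.character(meta$label %||% basename(path))
  )
}

#' @rdname read_uniaxial_record
#' @param record A [uniaxial_record()] to write.
#' @param write_metadata Also write a `<path>.meta` sidecar with the
#'   geometry, strain rate, label, and (for synthetic records) the generator
#'   spec including its seed?
#' @export
write_uniaxial_record <- function(record, path, write_metadata = TRUE) {
  readr::write_csv(as_tibble(record)[, c("extension_mm", "load_N")], path,
                   progress = FALSE)
  if (write_metadata) {
    geom <- attr(record, "geometry")
    meta <- list(
      gauge_length_mm = geom$gauge_length_mm,
      width_mm = geom$width_mm,
      thickness_mm = geom$thickness_mm,
      strain_rate = attr(record, "strain_rate"),
      label = attr(record, "label")
    )
    spec <- attr(record, "spec")
    if (!is.null(spec)) {
      meta <- c(meta, list(
        truth_c1_MPa = spec$c1, truth_c2 = spec$c2,
        noise_cv = spec$noise_cv, seed = spec$seed
      ))
    }
    write_keyvalue(meta, paste0(path, ".meta"))
  }
  invisible(path)
}

#' Read and write standardized stress-stretch curves
#'
#' Delimited text with columns `stretch` and `true_stress_MPa`.
#'
#' @param path File path.
#' @return A [stress_stretch_curve()].
#' @export
read_stress_stretch <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("stretch", "true_stress_MPa") %in% names(tab))) {
    abort(sprintf("'%s' must provide columns stretch and true_stress_MPa.", path))
  }
  stress_stretch_curve(tab$stretch, tab$true_stress_MPa)
}

#' @rdname read_stress_stretch
#' @param curve A [stress_stretch_curve()].
#' @export
write_stress_stretch <- function(curve, path) {
  readr::write_csv(
    tibble(stretch = curve$stretch, true_stress_MPa = curve$stress_MPa),
    path, progress = FALSE
  )
  invisible(path)
}

#' Serialize a fit report
#'
#' Writes the machine-readable `key = value` report of a [fit_veronda_westmann()]
#' result: `c1_MPa`, `c2`, `r_squared`, `n_points`, `converged`, the start
#' values and bounds, and a seed when the curve has synthetic provenance.
#'
#' @param fit A `vw_fit`.
#' @param path Output file.
#' @param seed Optional provenance seed recorded in the report.
#' @export
write_fit_report <- function(fit, path, seed = NULL) {
  stopifnot(inherits(fit, "vw_fit"))
  rep <- list(
    c1_MPa = fit$c1, c2 = fit$c2,
    r_squared = fit$r_squared, n_points = fit$n_points,
    converged = tolower(as.character(fit$converged)),
    init_c1 = fit$init[["c1"]], init_c2 = fit$init[["c2"]],
    bounds_c1 = paste(fit$bounds$c1, collapse = ".."),
    bounds_c2 = paste(fit$bounds$c2, collapse = "..")
  )
  if (!is.null(seed)) rep$seed <- seed
  write_keyvalue(rep, path)
}

# Serialize a pipeline_config (or any flat settings list) as key = value.
write_config <- function(config, path) {
  write_keyvalue(unclass(config), path)
}

read_config <- function(path) {
  kv <- read_keyvalue(path)
  pipeline_config(
    poly_degree = kv$poly_degree %||% 5L,
    grid_start = kv$grid_start %||% 1.0,
    grid_stop = kv$grid_stop %||% 2.0,
    grid_step = kv$grid_step %||% 0.01,
    stretch_mode = kv$stretch_mode %||% "engineering_strain",
    r2_warn_threshold = kv$r2_warn_threshold %||% 0.95
  )
}
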