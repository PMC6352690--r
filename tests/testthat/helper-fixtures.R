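# Shared fixtures: everything is generated in code at test time.

# The 11 catalog coefficient pairs, loaded once per test run.
catalog_pairs <- function() {
  sites <- site_catalog()
  list(c1 = sites$c1_MPa, c2 = sites$c2, location = sites$sample_location)
}

rel_err <- function(x, ref) abs(x - ref) / pmax(abs(ref), 1e-9)

# Preprocess while silencing the expected grid-clipping warning that noisy
# records produce when the yield trim shortens the strain domain.
quiet_pipeline <- function(record, config = pipeline_config()) {
  suppressWarnings(preprocess_pipeline(record, config))
}

# A record built directly from loads/extensions with default geometry.
make_record <- function(load_N, extension_mm = seq_along(load_N) - 1) {
  uniaxial_record(extension_mm, load_N, specimen_geometry())
}

# Noise-free generator spec with all artifacts disabled.
clean_spec <- function(...) {
  synthetic_spec(noise_cv = 0, n_slack_points = 0L, slack_extension_mm = 0,
                 post_yield_points = 0L, ...)
}
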