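test_that("slack trimming removes the leading negative-load region only", {
  rec <- make_record(c(-0.02, -0.01, 0.05, 0.3))
  out <- trim_negative_loads(rec)
  expect_equal(out$load_N, c(0.05, 0.3))
  expect_equal(processing_log(out)$n_removed, 2L)

  all_pos <- make_record(c(0.1, 0.2, 0.3))
  expect_equal(trim_negative_loads(all_pos)$load_N, all_pos$load_N)
  expect_equal(processing_log(trim_negative_loads(all_pos))$n_removed, 0L)

  expect_error(trim_negative_loads(make_record(c(-1, -1, -1))), "slack")
})

test_that("positive blips inside the slack region are trimmed with it", {
  rec <- make_record(c(-0.05, 0.01, -0.02, 0.1, 0.2, 0.3, 0.4, 0.5))
  out <- trim_negative_loads(rec)
  expect_equal(out$load_N, c(0.1, 0.2, 0.3, 0.4, 0.5))
  expect_equal(processing_log(out)$n_removed, 3L)
})

test_that("negative loads after sustained tension abort as a data-quality error", {
  rec <- make_record(c(-0.01, 0.1, 0.2, 0.3, 0.4, 0.5, -0.2, 0.6, 0.7, 0.8, 0.9, 1))
  expect_error(trim_negative_loads(rec), "grip failure")
})

test_that("yield truncation keeps data through the first load maximum", {
  expect_equal(trim_post_yield(make_record(c(0, 1, 3, 5, 4, 2)))$load_N, c(0, 1, 3, 5))
  mono <- make_record(c(0, 1, 2, 3))
  expect_equal(trim_post_yield(mono)$load_N, mono$load_N)
  # plateau: earliest index attaining the maximum wins (brute-force argmax)
  plateau <- c(0, 2, 5, 5, 3)
  expect_equal(trim_post_yield(make_record(plateau))$load_N,
               plateau[seq_len(which.max(plateau))])
})

test_that("origin shift subtracts the first sample and is idempotent", {
  rec <- uniaxial_record(c(0.4, 0.9), c(0.05, 1.0), specimen_geometry())
  out <- shift_to_origin(rec)
  expect_equal(out$extension_mm, c(0, 0.5))
  expect_equal(out$load_N, c(0, 0.95))
  expect_equal(shift_to_origin(out)$load_N, out$load_N)

  single <- uniaxial_record(0.4, 0.05, specimen_geometry())
  shifted <- shift_to_origin(single)
  expect_equal(c(shifted$extension_mm, shifted$load_N), c(0, 0))
})

test_that("trim and shift steps are idempotent in combination", {
  rec <- synth_raw_record(synthetic_spec(seed = 9))
  once <- shift_to_origin(trim_post_yield(trim_negative_loads(rec)))
  twice <- shift_to_origin(trim_post_yield(trim_negative_loads(once)))
  expect_equal(twice$extension_mm, once$extension_mm)
  expect_equal(twice$load_N, once$load_N)
})

test_that("engineering conversion uses nominal geometry (N/mm^2 = MPa)", {
  rec <- uniaxial_record(c(0, 17.5), c(0, 30), specimen_geometry(35, 10, 3))
  eng <- to_engineering(rec)
  expect_equal(eng$strain, c(0, 0.5))
  expect_equal(eng$stress_MPa, c(0, 1))
  expect_identical(attr(eng, "kind"), "engineering")
})

test_that("engineering-to-true conversion matches the closed forms and inverts", {
  eng <- stress_strain_curve(c(0, 0.5), c(3, 10), kind = "engineering")
  tru <- eng_to_true(eng)
  expect_equal(tru$stress_MPa, c(3, 15))
  expect_equal(tru$strain, c(0, log(1.5)))
  # round trip through the inverse maps
  back_strain <- expm1(tru$strain)
  back_stress <- tru$stress_MPa / (1 + back_strain)
  expect_equal(back_strain, eng$strain, tolerance = 1e-12)
  expect_equal(back_stress, eng$stress_MPa, tolerance = 1e-12)
  expect_error(eng_to_true(stress_strain_curve(-1.5, 1, kind = "engineering")),
               "domain")
})

test_that("polynomial trend is exact on polynomial data and tight on model curves", {
  x <- seq(0, 1, length.out = 50)
  y <- 2 - x + 0.5 * x^3 + 0.1 * x^5
  trend <- fit_poly_trend(stress_strain_curve(x, y, kind = "true",
                                              strain_kind = "engineering"))
  expect_equal(trend$r_squared, 1, tolerance = 1e-9)
  expect_equal(predict(trend, c(0.25, 0.75)),
               2 - c(0.25, 0.75) + 0.5 * c(0.25, 0.75)^3 + 0.1 * c(0.25, 0.75)^5,
               tolerance = 1e-8)

  lam <- standard_stretch_grid()
  vw <- stress_strain_curve(lam - 1, vw_uniaxial_stress(lam, 13.1, 0.21),
                            kind = "true", strain_kind = "engineering")
  expect_gt(fit_poly_trend(vw)$r_squared, 0.999)
})

test_that("degenerate trend inputs follow the stated conventions", {
  x <- seq(0, 1, length.out = 20)
  warns <- capture_warnings(
    trend <- fit_poly_trend(stress_strain_curve(x, rep(2, 20), kind = "true",
                                                strain_kind = "engineering"))
  )
  expect_identical(trend$r_squared, 0)
  expect_true(any(grepl("quality band", warns)))
  expect_error(
    fit_poly_trend(stress_strain_curve(x[1:5], x[1:5], kind = "true"), degree = 5),
    "Underdetermined"
  )
})

test_that("resampling clips to the fitted domain and never extrapolates silently", {
  x <- seq(0, 0.5, length.out = 40)
  trend <- fit_poly_trend(stress_strain_curve(x, 3 * x, kind = "true",
                                              strain_kind = "engineering"),
                          degree = 2)
  grid <- standard_stretch_grid() - 1
  expect_warning(out <- resample_standard_grid(trend, grid), "Clipped")
  expect_true(all(out$strain <= 0.5 + 1e-12))
  expect_equal(nrow(resample_standard_grid(trend, seq(0, 0.5, by = 0.01))), 51L)
  expect_error(resample_standard_grid(trend, numeric()), "non-empty")
  expect_error(predict(trend, 0.9), "forbidden")
})

test_that("stretch conversion honours the two modes", {
  eng0 <- stress_strain_curve(0, 1, kind = "engineering")
  expect_equal(to_stretch(eng0)$stretch, 1)

  tru <- stress_strain_curve(0.40546, 5, kind = "true")
  expect_equal(to_stretch(tru, "engineering_strain")$stretch, 1.5, tolerance = 1e-4)
  expect_equal(to_stretch(tru, "paper_literal")$stretch, 1.40546)

  eng1 <- stress_strain_curve(1, 5, kind = "engineering")
  expect_equal(to_stretch(eng1, "engineering_strain")$stretch, 2)
  expect_equal(to_stretch(eng1, "paper_literal")$stretch, 2)
  expect_error(to_stretch(eng1, "bogus"))
})

test_that("full pipeline recovers the generating curve from a clean record", {
  rec <- synth_raw_record(clean_spec(seed = 1))
  curve <- preprocess_pipeline(rec)
  truth <- generate_clean_curve(13.1, 0.21)
  expect_equal(curve$stretch, truth$stretch)
  sel <- curve$stretch >= 1.05 & curve$stretch <= 1.95
  expect_lt(max(rel_err(curve$stress_MPa[sel], truth$stress_MPa[sel])), 1e-3)
  # clean monotone record: steps i-iii are no-ops, visible in the log
  log <- processing_log(curve)
  expect_equal(log$n_removed[log$step %in% c("i", "ii")], c(0L, 0L))
  expect_match(log$note[log$step == "iii"], "0 mm, 0 N")
})

test_that("pipeline log reports the constructed slack and tail trim counts", {
  spec <- synthetic_spec(noise_cv = 0, n_slack_points = 20L,
                         post_yield_points = 10L, seed = 4)
  curve <- preprocess_pipeline(synth_raw_record(spec))
  log <- processing_log(curve)
  expect_equal(log$n_removed[log$step == "i"], 20L)
  expect_equal(log$n_removed[log$step == "ii"], 10L)
})

test_that("pipeline errors are tagged with their protocol step", {
  rec <- make_record(c(-1, -1, -1, -1))
  expect_error(preprocess_pipeline(rec), "step \\(i\\)")
})

test_that("the standard grid is reproducible bit-for-bit from its settings", {
  expect_identical(standard_stretch_grid(), seq(1, 2, by = 0.01))
  expect_identical(standard_stretch_grid(1.2, 1.8, 0.02), seq(1.2, 1.8, by = 0.02))
  expect_length(standard_stretch_grid(), 101L)
})
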