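test_that("modulus of a synthetic linear curve equals the generator slope", {
  grid <- standard_stretch_grid()
  lin <- stress_stretch_curve(grid, 2.0 * (grid - 1))
  expect_equal(elastic_modulus(lin, c(1.0, 1.1)), 2.0, tolerance = 1e-9)
  expect_error(elastic_modulus(lin, c(1.0, 1.004)), ">= 2")
})

test_that("a narrow toe window approaches the analytic initial tangent modulus", {
  curve <- generate_clean_curve(13.1, 0.21)
  slope <- elastic_modulus(curve, c(1.0, 1.01))
  h <- 1e-6
  tangent <- (vw_uniaxial_stress(1 + h, 13.1, 0.21) -
                vw_uniaxial_stress(1, 13.1, 0.21)) / h
  expect_lt(rel_err(slope, tangent), 0.02)
})

test_that("low/high moduli capture the toe and terminal regimes", {
  m <- low_high_moduli(generate_clean_curve(13.1, 0.21))
  expect_gt(m$e_high / m$e_low, 1)
  expect_equal(m$high_window, c(1.9, 2.0))

  # piecewise-linear toy: slopes 1 then 10, windows aligned to the pieces
  lam <- seq(1, 2, by = 0.01)
  toy <- stress_stretch_curve(
    lam, ifelse(lam <= 1.5, lam - 1, 0.5 + 10 * (lam - 1.5))
  )
  expect_equal(elastic_modulus(toy, c(1, 1.5)), 1, tolerance = 1e-9)
  expect_equal(elastic_modulus(toy, c(1.5, 2)), 10, tolerance = 1e-9)

  flat <- stress_stretch_curve(lam, rep(3, length(lam)))
  mf <- low_high_moduli(flat)
  expect_equal(mf$e_low, 0)
  expect_equal(mf$e_high, 0)
})

test_that("ultimate tensile stress is the curve maximum", {
  expect_equal(as.numeric(ultimate_tensile_stress(
    stress_stretch_curve(c(1, 1.2, 1.4, 1.6), c(0, 5, 16, 12))
  )), 16)
  mono <- generate_clean_curve(13.1, 0.21)
  uts <- ultimate_tensile_stress(mono)
  expect_equal(as.numeric(uts), mono$stress_MPa[[101]])
  expect_equal(attr(uts, "at_stretch"), 2)
  # against the independent finite-difference stress oracle at lambda = 2
  oracle <- uniaxial_stress_numeric(vw_model(13.1, 0.21), 2)
  expect_lt(rel_err(as.numeric(uts), oracle), 0.005)
})

test_that("UTS is invariant under grid refinement for monotone curves", {
  coarse <- generate_clean_curve(13.1, 0.21, standard_stretch_grid(1, 2, 0.01))
  fine <- generate_clean_curve(13.1, 0.21, standard_stretch_grid(1, 2, 0.002))
  expect_lt(rel_err(as.numeric(ultimate_tensile_stress(coarse)),
                    as.numeric(ultimate_tensile_stress(fine))), 0.005)
})

test_that("strain stiffening holds on every catalog fixture", {
  pairs <- catalog_pairs()
  for (k in seq_along(pairs$c1)) {
    m <- low_high_moduli(generate_clean_curve(pairs$c1[k], pairs$c2[k]))
    expect_gt(m$e_high, m$e_low)
  }
})

test_that("metric rows always carry their windows", {
  row <- tissue_metrics(generate_clean_curve(13.1, 0.21))
  expect_true(all(c("window_low_lo", "window_low_hi",
                    "window_high_lo", "window_high_hi") %in% names(row)))
  expect_equal(row$window_low_lo, 1.0)
  expect_equal(row$window_high_hi, 2.0)
})

test_that("repeatability summary follows the mean +/- sd convention", {
  one <- tissue_metrics(generate_clean_curve(13.1, 0.21))
  batch <- dplyr::bind_rows(one, one, one)
  s <- summarize_repeatability(batch)
  expect_equal(s$sd, rep(0, 3))
  expect_equal(s$n, rep(3L, 3))

  fake <- tibble::tibble(e_low_MPa = c(1, 2, 3))
  s2 <- summarize_repeatability(fake)
  expect_equal(s2$mean, 2)
  expect_equal(s2$sd, 1)
  expect_match(s2$formatted, "2.000 ± 1.000", fixed = TRUE)
  expect_error(summarize_repeatability(tibble::tibble()), "non-empty")
})

test_that("noisy repeatability batches centre on the ground truth", {
  # reference: the same pipeline applied to a noise-free record, so the
  # comparison isolates measurement noise from trend-approximation error
  truth <- tissue_metrics(preprocess_pipeline(synth_raw_record(
    synthetic_spec(noise_cv = 0, seed = 1L)
  )))
  batch <- synth_repeatability_batch(
    synthetic_spec(noise_cv = 0.05, seed = 1L), n_specimens = 36
  )
  metrics <- purrr::map(batch, function(rec) {
    tissue_metrics(quiet_pipeline(rec))
  }) |> purrr::list_rbind()
  s <- summarize_repeatability(metrics)
  # e_low and uts carry small noise-proportional systematic biases (trend
  # smoothing of the toe; yield trimming at the noisy load peak), so the
  # centering allowance is the noise CV itself when it exceeds 2 SE
  noise_cv <- 0.05
  for (col in c("e_low_MPa", "e_high_MPa", "uts_MPa")) {
    row <- s[s$metric == col, ]
    se <- row$sd / sqrt(row$n)
    expect_lt(abs(row$mean - truth[[col]]),
              max(2 * se, noise_cv * truth[[col]]))
  }
  # and the analytic model value is itself nearby
  analytic <- tissue_metrics(generate_clean_curve(13.1, 0.21))
  expect_lt(rel_err(s$mean[s$metric == "uts_MPa"], analytic$uts_MPa), 0.05)
})
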