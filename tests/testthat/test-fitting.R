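test_that("coefficient of determination matches hand arithmetic", {
  expect_equal(r_squared(c(0, 1, 2), c(0, 1, 2)), 1)
  expect_equal(r_squared(c(0, 1, 2), rep(1, 3)), 0)
  expect_equal(r_squared(c(0, 1, 2), c(0, 1, 3)), 0.5)
  expect_error(r_squared(1:3, 1:4), "length")
  # clipping keeps the raw value accessible
  expect_identical(r_squared(c(0, 1, 2), c(5, -4, 9)), 0)
  expect_lt(r_squared(c(0, 1, 2), c(5, -4, 9), clip = FALSE), 0)
  expect_warning(expect_equal(r_squared(c(2, 2, 2), c(2, 2, 2)), 0), "Constant")
})

test_that("noise-free curves from every catalog pair are recovered to 0.1%", {
  pairs <- catalog_pairs()
  for (k in seq_along(pairs$c1)) {
    fit <- fit_veronda_westmann(generate_clean_curve(pairs$c1[k], pairs$c2[k]))
    expect_lt(rel_err(fit$c1, pairs$c1[k]), 1e-3)
    expect_lt(rel_err(fit$c2, pairs$c2[k]), 1e-3)
    expect_gt(fit$r_squared, 0.9999)
    expect_true(fit$converged)
  }
})

test_that("degenerate fitting inputs raise errors", {
  grid <- standard_stretch_grid()
  expect_error(fit_veronda_westmann(stress_stretch_curve(grid, rep(0, 101))),
               "Degenerate")
  expect_error(fit_veronda_westmann(stress_stretch_curve(c(1, 1.5), c(0, 1))),
               "at least 3")
})

test_that("scaling the stresses scales c1 and leaves c2 unchanged", {
  curve <- generate_clean_curve(13.1, 0.21)
  base <- fit_veronda_westmann(curve)
  k <- 3.7
  scaled <- fit_veronda_westmann(
    stress_stretch_curve(curve$stretch, k * curve$stress_MPa)
  )
  expect_lt(rel_err(scaled$c1, k * base$c1), 1e-6)
  expect_lt(rel_err(scaled$c2, base$c2), 1e-6)
})

test_that("the fit never reports a worse objective than its start values", {
  set.seed(42)
  grid <- standard_stretch_grid()
  for (r in 1:5) {
    stress <- vw_uniaxial_stress(grid, 22, 0.26) * (1 + 0.05 * rnorm(101))
    init <- c(c1 = 10, c2 = 0.25)
    fit <- fit_veronda_westmann(stress_stretch_curve(grid, stress), init = init)
    rss_init <- sum((stress - vw_uniaxial_stress(grid, init[["c1"]], init[["c2"]]))^2)
    expect_lte(fit$rss, rss_init)
  }
})

test_that("repeated noisy fits are nearly unbiased (3% multiplicative noise)", {
  set.seed(1)
  grid <- standard_stretch_grid()
  est <- replicate(100, {
    stress <- vw_uniaxial_stress(grid, 27, 0.29) * (1 + 0.03 * rnorm(101))
    fit <- fit_veronda_westmann(stress_stretch_curve(grid, stress))
    c(fit$c1, fit$c2)
  })
  expect_lt(abs(mean(est[1, ]) - 27) / 27, 0.02)
  expect_lt(abs(mean(est[2, ]) - 0.29) / 0.29, 0.02)
  expect_lt(rel_err(mean(est[1, ]), 27), 0.05)
})

test_that("batch fitting summarizes parameters, not pooled data", {
  pairs <- catalog_pairs()
  curves <- lapply(seq_along(pairs$c1), function(k) {
    generate_clean_curve(pairs$c1[k], pairs$c2[k])
  })
  batch <- fit_batch(curves)
  expect_equal(batch$summary$n_fitted, 11L)
  expect_equal(batch$summary$n_excluded, 0L)
  expect_equal(batch$summary$mean_c1, mean(pairs$c1), tolerance = 1e-4)
  expect_equal(batch$summary$sd_c1, sd(pairs$c1), tolerance = 1e-4)
  expect_equal(batch$summary$sd_c2, sd(pairs$c2), tolerance = 1e-3)

  single <- fit_batch(curves[1])
  expect_equal(single$summary$sd_c1, 0)
  expect_equal(single$summary$mean_c1, batch$results$c1[[1]], tolerance = 1e-9)
})

test_that("a degenerate member is excluded from the batch summary, not fatal", {
  curves <- list(
    generate_clean_curve(13.1, 0.21),
    stress_stretch_curve(standard_stretch_grid(), rep(0, 101)),
    generate_clean_curve(16, 0.26)
  )
  batch <- fit_batch(curves)
  expect_equal(batch$summary$n_excluded, 1L)
  expect_equal(batch$summary$n_fitted, 2L)
  expect_match(batch$results$error[[2]], "Degenerate")
  expect_null(batch$fits[[2]])
})

test_that("tidy and glance expose the fit in tabular form", {
  fit <- fit_veronda_westmann(generate_clean_curve(13.1, 0.21))
  td <- tidy(fit)
  expect_equal(td$term, c("c1", "c2"))
  expect_equal(td$estimate, c(13.1, 0.21), tolerance = 1e-4)
  gl <- glance(fit)
  expect_equal(gl$n_points, 101L)
  expect_true(gl$converged)
})
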