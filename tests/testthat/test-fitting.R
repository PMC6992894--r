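# Slope fitting, the two-level (D, K) solve, and model verification.

test_that("through-origin sqrt(t) fit recovers exact slopes with R^2 = 1", {
  ts <- c(50, 150, 300, 650)
  co <- iso_contour_series(0.5, ts, 0.642 * sqrt(ts))
  fit <- fit_slope(co)
  expect_equal(fit$slope, 0.642, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$intercept_diagnostic$intercept, 0, tolerance = 1e-9)
  expect_equal(fit_slope(iso_contour_series(0.5, c(1, 4), c(1, 2)))$slope, 1)
  zero <- fit_slope(iso_contour_series(0.5, ts, rep(0, 4)))
  expect_true(zero$flagged)
  expect_equal(zero$slope, 0)
  expect_true(is.na(zero$r_squared))
})

test_that("noisy contour slopes stay close to the generative truth", {
  set.seed(11)
  ts <- c(50, 150, 300, 650)
  truth <- 0.642
  est <- replicate(200, {
    fit_slope(iso_contour_series(0.5, ts, truth * sqrt(ts) + rnorm(4, 0, 0.2)))$slope
  })
  # SE of the through-origin estimator: sigma / sqrt(sum(t))
  se <- 0.2 / sqrt(sum(ts))
  expect_lt(abs(mean(est) - truth), 3 * se / sqrt(200))
  expect_equal(sd(est), se, tolerance = 0.2)
})

test_that("the two-level solve reproduces the published parameter pairs", {
  std <- solve_DK(0.642, 0.5, 0.441, 0.9)
  expect_equal(std$D, 0.138, tolerance = 0.02)
  expect_equal(std$K, 2.233, tolerance = 0.02)
  gfp <- solve_DK(0.210, 0.5, 0.106, 0.9)
  expect_equal(gfp$D, 0.026, tolerance = 0.01)
  expect_equal(gfp$K, 1.404, tolerance = 0.01)
  # argument order does not matter
  swapped <- solve_DK(0.441, 0.9, 0.642, 0.5)
  expect_equal(swapped$D, std$D, tolerance = 1e-12)
})

test_that("solve_DK inverts slope_at_level over the admissible grid", {
  for (D in c(0.01, 0.05, 0.2, 0.6, 1)) {
    for (K in c(1.05, 1.4, 2.2, 3.5, 5)) {
      p <- penetration_params(D, K)
      s <- slope_at_level(p, c(0.5, 0.9))
      rec <- solve_DK(s[1], 0.5, s[2], 0.9)
      expect_equal(rec$D, D, tolerance = 1e-6)
      expect_equal(rec$K, K, tolerance = 1e-6)
    }
  }
})

test_that("solve_DK is scale-consistent and rejects inconsistent inputs", {
  base <- solve_DK(0.642, 0.5, 0.441, 0.9)
  for (c_scale in c(0.1, 3)) {
    scaled <- solve_DK(0.642 * c_scale, 0.5, 0.441 * c_scale, 0.9)
    expect_equal(scaled$D, base$D * c_scale^2, tolerance = 1e-9)
    expect_equal(scaled$K, base$K, tolerance = 1e-9)
  }
  expect_error(solve_DK(0.6, 0.5, 0.4, 0.5), class = "crpen_input_error")
  expect_error(solve_DK(0.4, 0.5, 0.6, 0.9), class = "crpen_input_error")
  expect_error(solve_DK(0.6, 0.5, -1, 0.9), class = "crpen_input_error")
  # slope ratio so extreme the implied K drops below 1
  expect_error(solve_DK(10, 0.5, 1, 0.9),
               class = "crpen_inconsistent_data_error")
})

test_that("profile R^2 scores exact, noisy and mis-specified models sensibly", {
  p <- std_params()
  zs <- seq(0, 24.5, by = 0.5)
  exact <- depth_profile(300, zs, fluorescence(p, 300, zs), normalized = TRUE)
  expect_equal(profile_r_squared(p, exact), 1)
  set.seed(99)
  r2_true <- r2_wrong <- numeric(50)
  wrong <- penetration_params(2 * p$D, p$K)
  for (i in 1:50) {
    noisy <- depth_profile(300, zs,
                           fluorescence(p, 300, zs) + rnorm(length(zs), 0, 0.02),
                           normalized = TRUE)
    r2_true[i] <- profile_r_squared(p, noisy)
    r2_wrong[i] <- profile_r_squared(wrong, noisy)
  }
  expect_true(all(r2_true > 0.95))
  expect_true(all(r2_wrong < r2_true))
  flat <- depth_profile(300, zs, rep(0.4, length(zs)), normalized = TRUE)
  expect_true(is.na(profile_r_squared(p, flat)))
})

test_that("derived constants match the closed-form expressions", {
  expect_equal(derived_constants(penetration_params(0.25, 2)),
               list(two_sqrt_D = 1, inv_K = 0.5))
  expect_equal(derived_constants(penetration_params(0.138, 1))$inv_K, 1)
})

test_that("fit_penetration assembles slopes, parameters and diagnostics", {
  spec <- tiny_spec()
  gen <- generate_series(spec)
  report <- fit_penetration(extract_profiles(gen))
  expect_s3_class(report, "fit_report")
  expect_equal(report$params$D, spec$params$D, tolerance = 0.02)
  expect_equal(report$params$K, spec$params$K, tolerance = 0.02)
  expect_length(report$slope_fits, 2)
  expect_true(all(report$profile_r_squared > 0.999))
  expect_equal(report$solver$slope_residual, 0, tolerance = 1e-9)
})
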