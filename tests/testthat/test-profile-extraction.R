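# From image stacks to normalized depth profiles and contour series.

test_that("mean_profile averages xy planes at and below the declared surface", {
  st <- array(3, dim = c(10, 4, 4))
  ser <- stack_series(list(st), times = 5, z_step = 0.5, surface_index = 3)
  prof <- mean_profile(ser, 1)
  expect_equal(prof$depths, seq(0, 3.5, by = 0.5))
  expect_equal(prof$intensity, rep(3, 8))
  expect_error(mean_profile(ser, 2), class = "crpen_input_error")
})

test_that("noiseless synthetic stacks reproduce the forward model exactly", {
  spec <- tiny_spec()
  gen <- generate_series(spec)
  for (i in seq_along(spec$times)) {
    prof <- mean_profile(gen$series, i)
    expect_equal(prof$intensity,
                 fluorescence(spec$params, spec$times[i], prof$depths),
                 tolerance = 1e-12)
  }
})

test_that("normalization is invariant to affine intensity rescaling", {
  spec <- tiny_spec()
  gen <- generate_series(spec)
  raw <- mean_profile(gen$series, 3)
  truth <- fluorescence(spec$params, raw$time, raw$depths)
  # same profile rescaled as a*model + b: absolute-background normalization
  scaled <- depth_profile(raw$time, raw$depths, 37.5 * raw$intensity + 4.2)
  norm <- normalize_profile(scaled, background = 4.2, relative = FALSE)
  expect_equal(norm$intensity, truth, tolerance = 1e-9)
  # relative background: fraction of the plateau, as generated
  spec_bg <- tiny_spec(background_fraction = 0.1)
  gen_bg <- generate_series(spec_bg)
  raw_bg <- mean_profile(gen_bg$series, 3)
  norm_bg <- normalize_profile(raw_bg, background = 0.1, relative = TRUE)
  expect_equal(norm_bg$intensity, truth, tolerance = 1e-9)
})

test_that("a profile without a saturated plateau is rejected as degenerate", {
  flat <- depth_profile(10, 0:9, rep(0.07, 10))
  expect_error(normalize_profile(flat, background = 0.07, relative = FALSE),
               class = "crpen_degenerate_profile_error")
})

test_that("contour depth interpolates the first downward crossing", {
  step <- depth_profile(10, 0:10, c(1, 1, 1, 1, 1, 1, 0, 0, 0, 0, 0),
                        normalized = TRUE)
  expect_equal(contour_depth(step, 0.5), 5.5)
  # monotone in level on a monotone profile
  spec <- tiny_spec()
  gen <- generate_series(spec)
  prof <- normalize_profile(mean_profile(gen$series, 2))
  depths <- vapply(c(0.9, 0.7, 0.5, 0.3), function(lv) contour_depth(prof, lv),
                   numeric(1))
  expect_true(all(diff(depths) > 0))
  # level above the plateau maximum is never crossed
  decayed <- depth_profile(10, 0:5, c(0.4, 0.3, 0.2, 0.1, 0.05, 0.01),
                           normalized = TRUE)
  expect_error(contour_depth(decayed, 0.5),
               class = "crpen_not_penetrated_error")
  expect_error(contour_depth(step, 1.5), class = "crpen_domain_error")
})

test_that("contour interpolation matches the reported HM20 half-level depth", {
  spec <- synthetic_spec(gfp_params(), times = c(50, 100), nx = 4, ny = 4,
                         n_planes = 40, z_step = 0.5, surface_index = 6)
  gen <- generate_series(spec)
  prof <- normalize_profile(mean_profile(gen$series, 2))
  expect_equal(contour_depth(prof, 0.5), 2.10, tolerance = 0.01)
})

test_that("masked extraction reduces to the plain mean and recovers the model", {
  spec <- tiny_spec()
  gen <- generate_series(spec)
  d <- dim(gen$series$stacks[[1]])
  everything <- array(TRUE, dim = d)
  m_all <- masked_profile(gen$series, 2, list(everything))
  expect_equal(m_all$intensity, mean_profile(gen$series, 2)$intensity)
  # disjoint masks over an identical signal agree with a single mask
  left <- array(FALSE, dim = d); left[, , 1:4] <- TRUE
  right <- array(FALSE, dim = d); right[, , 5:8] <- TRUE
  m_split <- masked_profile(gen$series, 2, list(left, right))
  expect_equal(m_split$intensity, m_all$intensity, tolerance = 1e-12)
  # single-voxel masks on a noiseless stack still recover the profile
  one_col <- array(FALSE, dim = d); one_col[, 3, 3] <- TRUE
  m_one <- masked_profile(gen$series, 2, list(one_col))
  expect_equal(m_one$intensity,
               fluorescence(spec$params, spec$times[2], m_one$depths),
               tolerance = 1e-12)
  empty <- array(FALSE, dim = d)
  expect_error(masked_profile(gen$series, 2, list(empty)),
               class = "crpen_input_error")
})

test_that("contour series follow slope*sqrt(t) and demand two usable times", {
  spec <- tiny_spec()
  gen <- generate_series(spec)
  profiles <- extract_profiles(gen)
  contours <- build_contours(profiles, levels = c(0.5, 0.9))
  for (co in contours) {
    pred <- slope_at_level(spec$params, co$level) * sqrt(co$times)
    expect_equal(co$depths, pred, tolerance = 0.02)
  }
  # the lower level always lies deeper
  expect_true(all(contours[[1]]$depths > contours[[2]]$depths))
  # only one usable time point: the 0.98 level is only crossed late
  early <- profiles[1]
  expect_error(build_contours(early, levels = 0.5),
               class = "crpen_insufficient_data_error")
})

test_that("the opt-in surface heuristic finds a sharp plateau edge", {
  st <- array(0.2, dim = c(10, 4, 4))
  st[1:5, , ] <- 1          # buffer + surface plane at the saturated level
  expect_equal(detect_surface(st), 5L)
  expect_error(detect_surface(matrix(1, 2, 2)), class = "crpen_input_error")
})
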