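# Forward penetration model: concentration field, saturation, contours.

test_that("concentration satisfies the boundary and initial conditions", {
  for (D in c(0.026, 0.138, 1)) {
    expect_equal(concentration(D, t = c(1, 50, 650), z = 0), c(1, 1, 1))
    expect_equal(concentration(D, t = 0, z = c(0.5, 3, 40)), c(0, 0, 0))
    # the z = 0, t = 0 corner takes the boundary value
    expect_equal(concentration(D, t = 0, z = 0), 1)
  }
  expect_error(concentration(0.1, t = -1, z = 0), class = "crpen_domain_error")
  expect_error(concentration(0.1, t = 1, z = -2), class = "crpen_domain_error")
  expect_error(concentration(-0.1, t = 1, z = 1), class = "crpen_parameter_error")
})

test_that("concentration hits the half-maximum at the inverse-erfc argument", {
  # erfcinv(0.5) frozen from the normal-quantile closed form -qnorm(0.25)/sqrt(2)
  x_half <- 0.476936276204470
  D <- 0.25; t <- 1
  z <- x_half * 2 * sqrt(D * t)
  expect_equal(concentration(D, t, z), 0.5, tolerance = 1e-12)
  expect_equal(erfcinv(0.5), x_half, tolerance = 1e-10)
})

test_that("erfcinv agrees with an independent special-function implementation", {
  y <- c(1e-6, 0.01, 0.1, 0.45, 0.9, 1, 1.3, 1.9)
  expect_equal(erfcinv(y), pracma::erfcinv(y), tolerance = 1e-9)
  expect_equal(erfc(erfcinv(y)), y, tolerance = 1e-11)
  expect_error(erfcinv(0), class = "crpen_domain_error")
  expect_error(erfcinv(2), class = "crpen_domain_error")
})

test_that("concentration is self-similar in z/sqrt(t) and monotone", {
  set.seed(42)
  for (i in 1:20) {
    D <- runif(1, 0.01, 1)
    t <- runif(1, 1, 1000)
    z <- runif(1, 0.1, 20)
    c_scale <- runif(1, 0.1, 10)
    expect_equal(concentration(D, t * c_scale^2, z * c_scale),
                 concentration(D, t, z), tolerance = 1e-12)
  }
  zs <- seq(0, 20, by = 0.5)
  cz <- concentration(0.138, 100, zs)
  expect_true(all(diff(cz) < 0))
  ts <- c(10, 50, 100, 500)
  ct <- concentration(0.138, ts, 5)
  expect_true(all(diff(ct) > 0))
})

test_that("fluorescence saturates exactly where concentration exceeds 1/K", {
  p <- std_params()
  zs <- seq(0, 25, by = 0.25)
  co <- concentration(p, 300, zs)
  fl <- fluorescence(p, 300, zs)
  expect_true(all(fl >= 0 & fl <= 1))
  expect_identical(fl == 1, co >= 1 / p$K)
  expect_equal(fl[co < 1 / p$K], p$K * co[co < 1 / p$K])
  # surface is always saturated; K = 1 disables saturation entirely
  expect_equal(fluorescence(p, 50, 0), 1)
  p1 <- penetration_params(0.138, 1)
  expect_equal(fluorescence(p1, 100, zs), concentration(p1, 100, zs))
})

test_that("fluorescence reproduces the HM20 sample's half-intensity depth", {
  # half-intensity contour slope 0.210 um/sqrt(s): depth 2.10 um at t = 100 s
  expect_equal(fluorescence(gfp_params(), t = 100, z = 2.10), 0.5,
               tolerance = 5e-3)
  expect_equal(isointensity_depth(gfp_params(), t = 400, level = 0.5), 4.20,
               tolerance = 5e-3)
})

test_that("isointensity depth inverts fluorescence and scales as sqrt(t)", {
  p <- std_params()
  for (level in c(0.2, 0.5, 0.9, 0.99)) {
    z <- isointensity_depth(p, t = 137, level = level)
    expect_equal(fluorescence(p, 137, z), level, tolerance = 1e-9)
  }
  expect_equal(isointensity_depth(p, t = 0, level = 0.5), 0)
  # exact slope identity and sqrt-time scaling
  ts <- c(13, 50, 400)
  expect_equal(isointensity_depth(p, ts, 0.5),
               slope_at_level(p, 0.5) * sqrt(ts), tolerance = 1e-13)
  expect_equal(isointensity_depth(p, 4 * ts, 0.9),
               2 * isointensity_depth(p, ts, 0.9), tolerance = 1e-12)
  expect_error(isointensity_depth(p, 10, level = 1.2),
               class = "crpen_domain_error")
  expect_equal(slope_at_level(penetration_params(0.3, 1), 1), 0)
})

test_that("thickness curves order levels and resins as the model demands", {
  p <- gfp_params()
  cur <- cr_thickness_curves(p, levels = c(0.5, 1), times = c(10, 60, 300, 1900))
  z05 <- cur$depth_um[cur$level == 0.5]
  z10 <- cur$depth_um[cur$level == 1]
  expect_true(all(z05 > z10))
  # sqrt-time scaling across the table
  cur4 <- cr_thickness_curves(p, levels = 0.5, times = 4 * c(10, 60, 300, 1900))
  expect_equal(cur4$depth_um, 2 * z05, tolerance = 1e-12)
  # K = 1 at level 1: saturation boundary stays at the surface
  flat <- cr_thickness_curves(penetration_params(0.2, 1), levels = 1,
                              times = c(1, 10, 100))
  expect_equal(flat$depth_um, c(0, 0, 0))
  expect_error(cr_thickness_curves(p, 0.5, numeric(0)),
               class = "crpen_domain_error")
  expect_error(cr_thickness_curves(p, 0.5, c(10, 5)),
               class = "crpen_input_error")
})

test_that("finite-difference solution reproduces the erfc closed form", {
  D <- 0.1; dz <- 0.1
  dt <- 0.25 * dz^2 / D            # half the stability bound
  fd <- fd_concentration(D, dz, dt, horizon = 20)
  exact <- concentration(D, 20, fd$depth_um)
  expect_lt(max(abs(fd$concentration - exact)), 1e-3)
  # penetrated mass grows as 2*sqrt(D*t/pi)
  mass <- sum((fd$concentration[-1] + fd$concentration[-nrow(fd)]) / 2) * dz
  expect_equal(mass, 2 * sqrt(D * 20 / pi), tolerance = 1e-3)
  # zero horizon returns the initial condition
  fd0 <- fd_concentration(D, dz, dt, horizon = 0)
  expect_equal(fd0$concentration, c(1, numeric(nrow(fd0) - 1)))
  expect_error(fd_concentration(D, dz, dt = dz^2 / D, horizon = 10),
               class = "crpen_parameter_error")
})
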