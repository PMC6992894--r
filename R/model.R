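#' Complementary error function and its inverse
#'
#' `erfc(x) = 2/sqrt(pi) * integral_x^Inf exp(-u^2) du`, evaluated through the
#' normal CDF. `erfcinv()` inverts it by bracketed root finding on this same
#' `erfc()` (Brent's method, absolute tolerance 1e-12), so the pair is exactly
#' self-consistent regardless of which special-function variant the platform
#' provides.
#'
#' @param x Numeric vector (for `erfc`).
#' @param y Numeric vector in (0, 2) (for `erfcinv`).
#' @return Numeric vector.
#' @export
erfc <- function(x) 2 * stats::pnorm(-sqrt(2) * x)

#' @rdname erfc
#' @export
erfcinv <- function(y) {
  if (any(!is.finite(y)) || any(y <= 0) || any(y >= 2))
    stop_domain("erfcinv is defined on (0, 2)")
  vapply(y, function(yi) {
    if (yi == 1) return(0)
    # erfc is decreasing: root lies in [0, hi] for y < 1, [lo, 0] for y > 1
    hi <- 1
    if (yi < 1) {
      while (erfc(hi) > yi) hi <- hi * 2
      lo <- 0
    } else {
      lo <- -1
      while (erfc(lo) < yi) lo <- lo * 2
      hi <- 0
    }
    stats::uniroot(function(x) erfc(x) - yi, c(lo, hi), tol = 1e-12)$root
  }, numeric(1))
}

check_tz <- function(t, z) {
  if (any(!is.finite(t)) || any(t < 0)) stop_domain("`t` must be finite and >= 0 (s)")
  if (any(!is.finite(z)) || any(z < 0)) stop_domain("`z` must be finite and >= 0 (um)")
}

#' Normalized penetrant concentration beneath the specimen surface
#'
#' Solution of Fick's second law in a semi-infinite medium held at constant
#' (normalized) surface concentration 1 with zero initial concentration:
#' `C(t, z) = erfc(z / (2*sqrt(D*t)))`. At `t = 0` the initial condition is
#' returned (0 for `z > 0`); at `z = 0`, `t > 0` the boundary value 1. The
#' `z = 0, t = 0` corner takes the boundary value 1 so that the field is the
#' pointwise limit of the `t > 0` solution.
#'
#' @param params A [penetration_params()] object, or a single diffusion
#'   coefficient `D` in um^2/s (the concentration field does not involve `K`).
#' @param t Time since buffer application, s. Recycled against `z`.
#' @param z Depth below the surface, um (`z = 0` is the surface, increasing
#'   downward).
#' @return Normalized concentration in `[0, 1]`, same length as the recycled
#'   `(t, z)` pair.
#' @examples
#' concentration(0.138, t = 100, z = c(0, 2, 5, 10))
#' @export
concentration <- function(params, t, z) {
  D <- if (is.numeric(params)) penetration_params(params)$D
       else as_penetration_params(params)$D
  check_tz(t, z)
  n <- max(length(t), length(z))
  t <- rep_len(t, n); z <- rep_len(z, n)
  out <- numeric(n)
  zero_t <- t == 0
  out[zero_t] <- ifelse(z[zero_t] == 0, 1, 0)
  pos <- !zero_t
  out[pos] <- erfc(z[pos] / (2 * sqrt(D * t[pos])))
  out
}

#' Normalized reactivated fluorescence intensity
#'
#' Concentration mapped through the saturation law: fluorescence is
#' `K * C(t, z)` where the normalized concentration is below the saturation
#' threshold `1/K`, and exactly 1 (all fluorophores converted to the
#' fluorescent dianion state) wherever `C(t, z) >= 1/K`. Continuous in `t`
#' and `z`; with `K = 1` it coincides with [concentration()].
#'
#' @inheritParams concentration
#' @param params A [penetration_params()] object.
#' @return Normalized intensity in `[0, 1]`.
#' @examples
#' p <- penetration_params(D = 0.026, K = 1.404)
#' fluorescence(p, t = 100, z = c(0, 1, 2.1, 5))
#' @export
fluorescence <- function(params, t, z) {
  params <- as_penetration_params(params)
  pmin(1, params$K * concentration(params, t, z))
}

#' Depth of an isointensity contour
#'
#' The depth `Z_p(t)` at which the normalized fluorescence equals level `p`:
#' `Z_p(t) = 2*sqrt(D*t) * erfcinv(p / K)`. For `p = 1` this is the boundary
#' of the saturated region. The depth grows exactly with the square root of
#' time; `Z_p(t) / sqrt(t)` is the constant returned by [slope_at_level()].
#'
#' @inheritParams fluorescence
#' @param level Normalized intensity level in (0, 1].
#' @return Depth in um (vectorized over `t`).
#' @examples
#' p <- penetration_params(D = 0.026, K = 1.404)
#' isointensity_depth(p, t = c(100, 400), level = 0.5)
#' @export
isointensity_depth <- function(params, t, level) {
  params <- as_penetration_params(params)
  if (any(!is.finite(t)) || any(t < 0)) stop_domain("`t` must be finite and >= 0 (s)")
  check_level(level, closed_top = TRUE)
  2 * sqrt(params$D * t) * erfcinv(level / params$K)
}

check_level <- function(level, closed_top = FALSE) {
  ok <- is.numeric(level) & is.finite(level) & level > 0 &
    (if (closed_top) level <= 1 else level < 1)
  if (!all(ok))
    stop_domain(sprintf("intensity levels must lie in (0, 1%s)",
                        if (closed_top) "]" else ""))
  invisible(level)
}

#' Penetration slope of an isointensity contour
#'
#' The constant of proportionality between contour depth and `sqrt(t)`:
#' `s_p = 2*sqrt(D) * erfcinv(p / K)`, in um per sqrt-second, so that
#' `isointensity_depth(params, t, p) == s_p * sqrt(t)` exactly. These slopes
#' are what a straight-line fit of measured contour depth against `sqrt(t)`
#' estimates, and the two-level system solved by [solve_DK()] inverts them.
#'
#' @inheritParams isointensity_depth
#' @return Slope in um/sqrt(s) (vectorized over `level`).
#' @examples
#' p <- penetration_params(D = 0.026, K = 1.404)
#' slope_at_level(p, c(0.5, 0.9))
#' @export
slope_at_level <- function(params, level) {
  params <- as_penetration_params(params)
  check_level(level, closed_top = TRUE)
  2 * sqrt(params$D) * vapply(level / params$K, function(y) erfcinv(y), numeric(1))
}

#' Chemical-reactivation thickness curves
#'
#' Forward prediction of CR thickness `Z_p(t)` for each requested intensity
#' level over a time grid. Because the model is self-similar in `z/sqrt(t)`,
#' every curve is `slope * sqrt(t)`; lower levels always lie deeper
#' (`Z_0.5 >= Z_1.0` at every time).
#'
#' @inheritParams fluorescence
#' @param levels Intensity levels in (0, 1].
#' @param times Strictly increasing, non-empty time grid, s.
#' @return A data.frame with columns `time_s`, `level`, `depth_um`.
#' @examples
#' p <- penetration_params(D = 0.026, K = 1.404)
#' head(cr_thickness_curves(p, levels = c(0.5, 1), times = c(60, 300, 1200)))
#' @export
cr_thickness_curves <- function(params, levels = c(0.5, 1), times) {
  params <- as_penetration_params(params)
  if (length(times) == 0L || any(!is.finite(times)) || any(times < 0))
    stop_domain("`times` must be a non-empty vector of finite times >= 0")
  if (is.unsorted(times, strictly = TRUE))
    stop_input("`times` must be strictly increasing")
  check_level(levels, closed_top = TRUE)
  slopes <- slope_at_level(params, levels)
  out <- expand.grid(time_s = times, level = levels,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$depth_um <- slopes[match(out$level, levels)] * sqrt(out$time_s)
  out[order(out$level, out$time_s), , drop = FALSE]
}

#' Finite-difference solution of the penetration diffusion equation
#'
#' Explicit (FTCS) integration of `dC/dt = D d2C/dz2` with surface boundary
#' `C(t, 0) = 1`, initial condition `C(0, z > 0) = 0`, and a Dirichlet zero
#' far boundary. Kept deliberately independent of the closed-form erfc
#' solution so the two can validate each other.
#'
#' The far boundary defaults to `10 * sqrt(D * horizon)`, where the exact
#' semi-infinite solution is `erfc(5) ~ 1.5e-12` — far below grid error.
#'
#' @inheritParams concentration
#' @param dz Grid spacing, um.
#' @param dt Time step, s. Must satisfy the stability condition
#'   `D * dt / dz^2 <= 0.5`; the step actually used is `horizon` divided into
#'   an integer number of steps no larger than `dt`.
#' @param horizon Final time, s.
#' @param depth Domain depth, um. Defaults to `10 * sqrt(D * horizon)`.
#' @return A data.frame with columns `depth_um` and `concentration` giving
#'   the profile at `t = horizon` (at `horizon = 0`, the initial condition).
#' @examples
#' fd <- fd_concentration(0.1, dz = 0.5, dt = 0.5, horizon = 50)
#' max(abs(fd$concentration - concentration(0.1, 50, fd$depth_um)))
#' @export
fd_concentration <- function(params, dz, dt, horizon, depth = NULL) {
  D <- if (is.numeric(params)) penetration_params(params)$D
       else as_penetration_params(params)$D
  if (dz <= 0 || dt <= 0 || horizon < 0)
    stop_domain("`dz`, `dt` must be > 0 and `horizon` >= 0")
  r <- D * dt / dz^2
  if (r > 0.5 + 1e-12)
    stop_parameter(sprintf(
      "unstable explicit step: D*dt/dz^2 = %.3g exceeds the 0.5 bound", r))
  if (is.null(depth)) depth <- max(10 * sqrt(D * max(horizon, dt)), 10 * dz)
  z <- seq(0, depth, by = dz)
  nz <- length(z)
  C <- c(1, numeric(nz - 1))              # t = 0: surface at 1, bulk at 0
  if (horizon > 0) {
    n_steps <- ceiling(horizon / dt - 1e-9)
    dt_used <- horizon / n_steps
    r <- D * dt_used / dz^2
    i <- 2:(nz - 1)
    for (s in seq_len(n_steps)) {
      C[i] <- C[i] + r * (C[i + 1L] - 2 * C[i] + C[i - 1L])
      # boundaries C[1] = 1 and C[nz] = 0 are never updated
    }
  }
  data.frame(depth_um = z, concentration = C)
}
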