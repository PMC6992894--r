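#' Fit a square-root-of-time penetration slope
#'
#' Least-squares fit of contour depth against `sqrt(t)` through the origin:
#' the erfc model forces `Z_p(0) = 0`, so no intercept is estimated. The
#' determination coefficient is computed about the mean of the depths
#' (`R^2 = 1 - SS_res / SS_tot`), making it comparable across fitting
#' conventions. A free-intercept fit is reported as a diagnostic only; it
#' never feeds [solve_DK()].
#'
#' @param series An [iso_contour_series()] with at least 2 points at `t > 0`.
#' @return An object of class `slope_fit`: fields `level`, `slope`
#'   (um/sqrt(s)), `r_squared`, `n_points`, `flagged` (TRUE when all depths
#'   are zero so R^2 is undefined), and `intercept_diagnostic` (intercept and
#'   slope of the free-intercept fit).
#' @export
fit_slope <- function(series) {
  stopifnot(inherits(series, "iso_contour_series"))
  t <- series$times; z <- series$depths
  if (length(t) < 2L)
    crpen_stop("need at least 2 contour points to fit a slope",
               "crpen_insufficient_data_error")
  if (any(t <= 0)) stop_input("contour times must be > 0 for a sqrt(t) fit")
  rt <- sqrt(t)
  flagged <- all(z == 0)
  slope <- if (flagged) 0 else sum(rt * z) / sum(t)
  ss_res <- sum((z - slope * rt)^2)
  ss_tot <- sum((z - mean(z))^2)
  r2 <- if (flagged || ss_tot == 0) NA_real_ else 1 - ss_res / ss_tot
  ic <- stats::lm.fit(cbind(1, rt), z)$coefficients
  structure(
    list(level = series$level, slope = slope, r_squared = r2,
         n_points = length(t), flagged = flagged,
         intercept_diagnostic = list(intercept = unname(ic[1]),
                                     slope = unname(ic[2]))),
    class = "slope_fit"
  )
}

#' @export
print.slope_fit <- function(x, ...) {
  cat(sprintf("Slope fit at level %.3g: %.4g um/sqrt(s) (R^2 = %s, n = %d)%s\n",
              x$level, x$slope,
              if (is.na(x$r_squared)) "undefined" else format(signif(x$r_squared, 4)),
              x$n_points, if (x$flagged) " [flagged: all depths zero]" else ""))
  invisible(x)
}

#' Solve the two-level system for D and K
#'
#' Two isointensity contour slopes determine both model parameters through
#' `K * erfc(s_i / (2*sqrt(D))) = p_i`. Writing `a = 1 / (2*sqrt(D))`, `K`
#' is eliminated via `erfc(s1*a) / erfc(s2*a) = p1 / p2`, which is strictly
#' monotone in `a`, so the root is unique and bracketed. The bracket upper
#' end is chosen so `erfc(s2 * a_max) > p2 * 1e-12`; the root is refined by
#' Brent's method to absolute tolerance 1e-12, then `K = p1 / erfc(s1 * a)`
#' and `D = 1 / (4 * a^2)`. The forward slopes implied by the solution are
#' recomputed and must match the inputs to 1e-9 relative.
#'
#' @param s1,s2 Contour slopes, um/sqrt(s), both > 0.
#' @param p1,p2 The corresponding intensity levels in (0, 1), `p1 != p2`.
#'   Consistency with a monotone profile requires the higher level to have
#'   the smaller slope.
#' @param sample Optional label for the returned parameters.
#' @return A [penetration_params()] object with attribute `solver`
#'   (bracket, iterations estimate, residual of the slope round trip).
#' @examples
#' solve_DK(0.642, 0.5, 0.441, 0.9)   # FITC/GMA standard sample
#' solve_DK(0.210, 0.5, 0.106, 0.9)   # HM20-embedded GFP brain
#' @export
solve_DK <- function(s1, p1, s2, p2, sample = NULL) {
  check_level(c(p1, p2))
  if (p1 == p2) stop_input("the two levels must differ")
  if (s1 <= 0 || s2 <= 0) stop_input("slopes must be > 0")
  # canonical order: p1 the lower level
  if (p1 > p2) { tmp <- s1; s1 <- s2; s2 <- tmp; tmp <- p1; p1 <- p2; p2 <- tmp }
  if (s1 <= s2)
    stop_input("inconsistent slopes: the higher level must have the smaller slope")
  a_max <- erfcinv(p2 * 1e-12) / s2
  f <- function(a) erfc(s1 * a) / erfc(s2 * a) - p1 / p2
  lo <- 1e-6
  if (f(lo) <= 0 || f(a_max) >= 0)
    crpen_stop("no sign change in the root bracket: the slope/level pair admits no solution",
               "crpen_no_solution_error")
  root <- stats::uniroot(f, c(lo, a_max), tol = 1e-12)
  a <- root$root
  K <- p1 / erfc(s1 * a)
  D <- 1 / (4 * a^2)
  if (K < 1)
    crpen_stop(sprintf("fitted K = %.4g < 1: slopes are inconsistent with a saturating profile", K),
               "crpen_inconsistent_data_error")
  params <- penetration_params(D, K, sample)
  fwd <- slope_at_level(params, c(p1, p2))
  resid <- max(abs(fwd - c(s1, s2)) / c(s1, s2))
  if (resid > 1e-9)
    crpen_stop(sprintf("slope round trip failed (relative residual %.2g)", resid),
               "crpen_no_solution_error")
  attr(params, "solver") <- list(a = a, bracket = c(lo, a_max),
                                 iterations = root$iter,
                                 f_residual = root$estim.prec,
                                 slope_residual = resid)
  params
}

#' Determination coefficient of a model-vs-profile comparison
#'
#' Evaluates the forward model at the measured depths and time and returns
#' `R^2 = 1 - sum((meas - model)^2) / sum((meas - mean(meas))^2)`. The raw
#' value is reported — it can be negative for a model worse than the mean;
#' no clipping is applied. A constant measured profile has undefined R^2 and
#' returns `NA`.
#'
#' @param params A [penetration_params()] object.
#' @param profile A normalized [depth_profile()].
#' @return A single numeric R^2 (possibly `NA`).
#' @export
profile_r_squared <- function(params, profile) {
  params <- as_penetration_params(params)
  stopifnot(inherits(profile, "depth_profile"))
  meas <- profile$intensity
  ss_tot <- sum((meas - mean(meas))^2)
  if (ss_tot == 0) return(NA_real_)
  model <- fluorescence(params, profile$time, profile$depths)
  1 - sum((meas - model)^2) / ss_tot
}

#' Estimate penetration parameters from normalized depth profiles
#'
#' The full estimation stage: build the two isointensity contour series,
#' fit each slope against `sqrt(t)`, solve the two-level system for
#' `(D, K)`, and score the fitted model against every input profile.
#'
#' @param profiles List of normalized [depth_profile()] objects spanning at
#'   least two time points.
#' @param levels Exactly two intensity levels in (0, 1); default
#'   `c(0.5, 0.9)`.
#' @param sample Optional sample label.
#' @return An object of class `fit_report`: `params`
#'   ([penetration_params()]), `slope_fits` (two [fit_slope()] results),
#'   `profile_r_squared` (named by time), and `solver` diagnostics.
#' @export
fit_penetration <- function(profiles, levels = c(0.5, 0.9), sample = NULL) {
  if (length(levels) != 2L) stop_input("exactly two levels are required")
  contours <- build_contours(profiles, levels)
  fit_penetration_from_contours(contours, sample = sample, profiles = profiles)
}

#' @rdname fit_penetration
#' @param contours A list of exactly two [iso_contour_series()] (as produced
#'   by [build_contours()] or read from a contour CSV).
#' @export
fit_penetration_from_contours <- function(contours, sample = NULL,
                                          profiles = NULL) {
  if (!is.list(contours) || length(contours) != 2L)
    stop_input("exactly two contour series are required")
  fits <- lapply(contours, fit_slope)
  if (any(vapply(fits, function(f) f$flagged, logical(1))))
    crpen_stop("a contour has all-zero depths; slopes cannot determine (D, K)",
               "crpen_insufficient_data_error")
  params <- solve_DK(fits[[1]]$slope, fits[[1]]$level,
                     fits[[2]]$slope, fits[[2]]$level, sample = sample)
  r2 <- NULL
  if (!is.null(profiles)) {
    r2 <- vapply(profiles, function(p) profile_r_squared(params, p), numeric(1))
    names(r2) <- vapply(profiles, function(p) format(p$time), character(1))
  }
  structure(
    list(params = params, slope_fits = fits, profile_r_squared = r2,
         solver = attr(params, "solver")),
    class = "fit_report"
  )
}

#' @export
print.fit_report <- function(x, ...) {
  cat("Penetration model fit\n")
  print(x$params)
  for (f in x$slope_fits) {
    cat("  "); print(f)
  }
  if (!is.null(x$profile_r_squared)) {
    cat("  profile R^2 by time (s):\n")
    print(round(x$profile_r_squared, 4))
  }
  invisible(x)
}

#' Serialize a fit report to JSON
#'
#' @param report A `fit_report` from [fit_penetration()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fit_report_json <- function(report, path) {
  stopifnot(inherits(report, "fit_report"))
  p <- report$params
  out <- list(
    params = list(D_um2_per_s = p$D, K = p$K,
                  sample = if (is.null(p$sample)) NA_character_ else p$sample),
    derived = derived_constants(p),
    slope_fits = lapply(report$slope_fits, function(f)
      list(level = f$level, slope = f$slope, r_squared = f$r_squared,
           n_points = f$n_points,
           intercept_diagnostic = f$intercept_diagnostic)),
    profile_r_squared = if (is.null(report$profile_r_squared)) NULL else
      as.list(report$profile_r_squared),
    solver = report$solver[c("a", "bracket", "iterations", "slope_residual")]
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
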