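#' Mean depth profile of a stack
#'
#' Averages every pixel of each xy plane at or below the declared surface,
#' which is how the fluorescence of a homogeneous, isotropic specimen is
#' summarized to one value per depth. Depth is `(plane - surface_index) *
#' z_step`; planes above the surface (buffer region) are excluded because
#' the model domain is `z >= 0`.
#'
#' @param series A [stack_series()].
#' @param t_index 1-based index into the series' time points.
#' @return A raw (unnormalized) [depth_profile()].
#' @export
mean_profile <- function(series, t_index) {
  stopifnot(inherits(series, "stack_series"))
  t_index <- as.integer(t_index)
  if (t_index < 1L || t_index > length(series$times))
    stop_input("`t_index` out of range")
  stack <- series$stacks[[t_index]]
  planes <- series$surface_index:dim(stack)[1]
  vals <- apply(stack[planes, , , drop = FALSE], 1, mean)
  depth_profile(
    time = series$times[t_index],
    depths = (planes - series$surface_index) * series$z_step,
    intensity = vals
  )
}

#' Fiber-masked depth profile
#'
#' For specimens where intensity is uniform only along sparse structures
#' (e.g. nerve fibers in resin-embedded brain), the per-plane mean is taken
#' over each fiber's mask separately and the per-fiber means are then
#' averaged at each depth. Planes where a fiber's mask is empty are omitted
#' from that fiber; depths where every mask is empty are dropped from the
#' profile.
#'
#' @inheritParams mean_profile
#' @param masks A list of logical 3-D arrays (one per fiber) with the same
#'   dimensions as the stacks.
#' @return A raw [depth_profile()].
#' @export
masked_profile <- function(series, t_index, masks) {
  stopifnot(inherits(series, "stack_series"))
  t_index <- as.integer(t_index)
  if (t_index < 1L || t_index > length(series$times))
    stop_input("`t_index` out of range")
  if (!is.list(masks) || length(masks) == 0L)
    stop_input("`masks` must be a non-empty list of logical arrays")
  stack <- series$stacks[[t_index]]
  d <- dim(stack)
  for (m in masks) {
    if (!identical(dim(m), d)) stop_input("mask dimensions must match the stacks")
  }
  if (!any(vapply(masks, any, logical(1))))
    stop_input("all masks are empty")
  planes <- series$surface_index:d[1]
  per_fiber <- vapply(masks, function(m) {
    vapply(planes, function(p) {
      sel <- m[p, , ]
      if (!any(sel)) NA_real_ else mean(stack[p, , ][sel])
    }, numeric(1))
  }, numeric(length(planes)))
  per_fiber <- matrix(per_fiber, nrow = length(planes))
  vals <- rowMeans(per_fiber, na.rm = TRUE)
  keep <- is.finite(vals)
  if (!any(keep)) stop_input("masks cover no below-surface voxels")
  depth_profile(
    time = series$times[t_index],
    depths = ((planes - series$surface_index) * series$z_step)[keep],
    intensity = vals[keep]
  )
}

#' Normalize a raw depth profile
#'
#' Subtracts background fluorescence and rescales so the saturated plateau
#' near the surface sits at 1. The plateau is estimated from the shallowest
#' below-surface samples whose raw value lies within 2% of the profile
#' maximum (at least 3 samples when available) — a near-surface window rather
#' than the global maximum, so single hot pixels deeper down cannot set the
#' scale. Small negative values left after background subtraction are
#' clipped to 0.
#'
#' @param profile A raw [depth_profile()].
#' @param background Background fluorescence. With `relative = TRUE` (the
#'   default) it is a fraction of the estimated plateau — e.g. `0.1` for
#'   GFP-labeled tissue with slight autofluorescence; with
#'   `relative = FALSE` it is on the raw intensity scale.
#' @param relative Interpret `background` as a fraction of the plateau?
#' @return A normalized [depth_profile()] with plateau at 1.
#' @export
normalize_profile <- function(profile, background = 0, relative = TRUE) {
  stopifnot(inherits(profile, "depth_profile"))
  if (!is.numeric(background) || length(background) != 1L || background < 0)
    stop_input("`background` must be a single number >= 0")
  v <- profile$intensity
  plateau <- estimate_plateau(v)
  bg <- if (relative) background * plateau else background
  if (plateau <= bg || plateau <= 0)
    crpen_stop(
      "plateau estimate does not exceed the background: the profile has no saturated region yet",
      "crpen_degenerate_profile_error")
  x <- (v - bg) / (plateau - bg)
  x[x < 0] <- 0
  depth_profile(profile$time, profile$depths, x, normalized = TRUE)
}

# plateau = mean of the (up to) 3 shallowest samples lying within 2% of the
# profile maximum; depths are assumed increasing, so these sit at the top of
# the saturated region and deeper, already-decaying values cannot bias the
# estimate downward
estimate_plateau <- function(v) {
  cand <- which(v >= 0.98 * max(v))
  mean(v[cand[seq_len(min(3L, length(cand)))]])
}

#' Depth at which a profile crosses an intensity level
#'
#' Scans the profile from the surface downward and linearly interpolates
#' within the first interval where the intensity drops from at or above
#' `level` to below it. The first-crossing rule makes the result
#' deterministic on noisy, non-monotone tails and matches the monotone
#' physical model.
#'
#' @param profile A normalized [depth_profile()].
#' @param level Intensity level in (0, 1).
#' @return Depth in um.
#' @export
contour_depth <- function(profile, level) {
  stopifnot(inherits(profile, "depth_profile"))
  check_level(level)
  v <- profile$intensity
  z <- profile$depths
  n <- length(v)
  if (n >= 2L) {
    above <- v[-n] >= level
    below_next <- v[-1] < level
    k <- which(above & below_next)
    if (length(k)) {
      i <- k[1]
      return(z[i] + (v[i] - level) / (v[i] - v[i + 1L]) * (z[i + 1L] - z[i]))
    }
  }
  crpen_stop(
    sprintf("level %.3g is never crossed: contour has not yet penetrated the sampled depths",
            level),
    "crpen_not_penetrated_error")
}

#' Build isointensity contour series from profiles
#'
#' Evaluates [contour_depth()] for each level across a list of normalized
#' profiles, dropping time points where the level has not yet been crossed.
#' At least two usable time points are required per level for the subsequent
#' square-root-of-time fit.
#'
#' @param profiles List of normalized [depth_profile()] objects.
#' @param levels Intensity levels in (0, 1), default the `I0.5`/`I0.9`
#'   contour pair used for parameter estimation.
#' @return A list of [iso_contour_series()], one per level.
#' @export
build_contours <- function(profiles, levels = c(0.5, 0.9)) {
  if (!is.list(profiles) || length(profiles) == 0L)
    stop_input("`profiles` must be a non-empty list of depth profiles")
  check_level(levels)
  lapply(levels, function(lv) {
    times <- numeric(0); depths <- numeric(0)
    for (p in profiles) {
      d <- tryCatch(contour_depth(p, lv),
                    crpen_not_penetrated_error = function(e) NA_real_)
      if (is.finite(d)) {
        times <- c(times, p$time)
        depths <- c(depths, d)
      }
    }
    if (length(times) < 2L)
      crpen_stop(
        sprintf("level %.3g crossed at fewer than 2 time points; cannot fit a contour",
                lv),
        "crpen_insufficient_data_error")
    iso_contour_series(lv, times, depths)
  })
}
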