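#' Time series of 3-D image stacks
#'
#' Container for the raw input of the pipeline: one 3-D intensity array per
#' time point, indexed `(z, y, x)`, with z calibration and the declared
#' surface plane. The surface plane is acquisition metadata (stacks are
#' typically recorded starting some planes above the block face, e.g. 10 um
#' of buffer above the specimen); it is never guessed silently, though
#' [detect_surface()] offers an explicit heuristic.
#'
#' @param stacks List of 3-D numeric arrays, all of identical dimension
#'   `(n_planes, ny, nx)`.
#' @param times Strictly increasing times, s, one per stack.
#' @param z_step Plane spacing, um.
#' @param surface_index 1-based index of the plane at depth `z = 0` (the
#'   specimen surface); planes with smaller index lie above the surface.
#' @return An object of class `stack_series`.
#' @export
stack_series <- function(stacks, times, z_step, surface_index) {
  if (!is.list(stacks) || length(stacks) == 0L)
    stop_input("`stacks` must be a non-empty list of 3-D arrays")
  dims <- lapply(stacks, dim)
  if (any(vapply(dims, length, 1L) != 3L))
    stop_input("each stack must be a 3-D array indexed (z, y, x)")
  if (length(unique(dims)) != 1L)
    stop_input("all stacks must share the same dimensions")
  if (length(times) != length(stacks))
    stop_input("`times` must have one entry per stack")
  if (is.unsorted(times, strictly = TRUE))
    stop_input("`times` must be strictly increasing")
  if (!is.numeric(z_step) || length(z_step) != 1L || z_step <= 0)
    stop_input("`z_step` must be a single positive number (um)")
  n_planes <- dims[[1]][1]
  surface_index <- as.integer(surface_index)
  if (surface_index < 1L || surface_index > n_planes)
    stop_input("`surface_index` must be a valid plane index")
  structure(
    list(stacks = stacks, times = as.numeric(times), z_step = z_step,
         surface_index = surface_index),
    class = "stack_series"
  )
}

#' @export
print.stack_series <- function(x, ...) {
  d <- dim(x$stacks[[1]])
  cat(sprintf(
    "Stack series: %d time points (%s s), %d planes of %dx%d, z step %g um\n",
    length(x$times), paste(format(x$times), collapse = ", "),
    d[1], d[2], d[3], x$z_step))
  cat(sprintf("  surface at plane %d (%d plane(s) above the specimen)\n",
              x$surface_index, x$surface_index - 1L))
  invisible(x)
}

#' Heuristic surface-plane detection
#'
#' Scanning from the top of the stack downward, returns the index of the
#' first plane whose xy-mean drops below `frac` of the maximum plane mean.
#' The plane before the drop is taken as the last fully saturated (buffer or
#' plateau) plane, so the returned index is the estimated surface. This is an
#' explicit opt-in: surface placement errors bias contour slopes, so
#' [stack_series()] always takes the declared index.
#'
#' @param stack A 3-D array indexed `(z, y, x)`.
#' @param frac Fraction of the maximum plane mean defining the drop
#'   (default 0.98).
#' @return A 1-based plane index.
#' @export
detect_surface <- function(stack, frac = 0.98) {
  if (length(dim(stack)) != 3L) stop_input("`stack` must be a 3-D array")
  plane_means <- apply(stack, 1, mean)
  below <- which(plane_means < frac * max(plane_means))
  if (length(below) == 0L) return(1L)
  max(1L, below[1] - 1L)
}

#' Depth profile of normalized (or raw) intensity
#'
#' One intensity value per depth below the surface at a single time point —
#' the unit the pipeline passes between stages.
#'
#' @param time Acquisition time, s.
#' @param depths Depths below the surface, um, non-negative and increasing.
#' @param intensity Intensity values, one per depth.
#' @param normalized Logical; `TRUE` once [normalize_profile()] has scaled
#'   the plateau to 1.
#' @return An object of class `depth_profile`.
#' @export
depth_profile <- function(time, depths, intensity, normalized = FALSE) {
  if (length(depths) != length(intensity) || length(depths) == 0L)
    stop_input("`depths` and `intensity` must be non-empty and equal length")
  if (any(depths < 0) || is.unsorted(depths, strictly = TRUE))
    stop_input("`depths` must be non-negative and strictly increasing")
  structure(
    list(time = as.numeric(time), depths = as.numeric(depths),
         intensity = as.numeric(intensity), normalized = isTRUE(normalized)),
    class = "depth_profile"
  )
}

#' @export
print.depth_profile <- function(x, ...) {
  cat(sprintf("Depth profile at t = %g s: %d samples, %g-%g um%s\n",
              x$time, length(x$depths), min(x$depths), max(x$depths),
              if (x$normalized) " (normalized)" else " (raw)"))
  invisible(x)
}

#' @export
as.data.frame.depth_profile <- function(x, ...) {
  data.frame(time_s = x$time, depth_um = x$depths, intensity = x$intensity)
}

#' Isointensity contour series
#'
#' The `(time, depth)` pairs at which a profile crosses a fixed normalized
#' intensity level; input to [fit_slope()].
#'
#' @param level Normalized intensity level in (0, 1).
#' @param times Times, s.
#' @param depths Contour depths, um, one per time.
#' @return An object of class `iso_contour_series`.
#' @export
iso_contour_series <- function(level, times, depths) {
  check_level(level)
  if (length(times) != length(depths))
    stop_input("`times` and `depths` must have equal length")
  if (any(depths < 0)) stop_input("contour depths must be non-negative")
  structure(
    list(level = as.numeric(level), times = as.numeric(times),
         depths = as.numeric(depths)),
    class = "iso_contour_series"
  )
}

#' @export
print.iso_contour_series <- function(x, ...) {
  cat(sprintf("Isointensity contour I%.2g: %d time points\n",
              x$level, length(x$times)))
  invisible(x)
}

#' @export
as.data.frame.iso_contour_series <- function(x, ...) {
  data.frame(level = x$level, time_s = x$times, depth_um = x$depths)
}
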