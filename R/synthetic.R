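#' Specification for synthetic reactivation stack series
#'
#' A complete generative description of a fixture dataset: the forward
#' model parameters, acquisition geometry, photon scale, background,
#' noise model and seed. With the same spec (same seed) the generated
#' series is bit-identical.
#'
#' Voxel means below the surface follow the forward model:
#' `photon_scale * (background_fraction + (1 - background_fraction) *
#' fluorescence(params, t, z))`. Planes above the surface image the buffer
#' and sit at the saturated value. In `"fibers"` mode the signal term (not
#' the background) is confined to sparse tube-like structures built from
#' seeded 3-D random walks, mimicking nerve fibers in embedded brain tissue.
#'
#' @param params A [penetration_params()] object (the generative truth).
#' @param times Strictly increasing acquisition times, s (>= 2 for a series).
#' @param nx,ny Lateral extent in pixels.
#' @param n_planes Number of z planes.
#' @param z_step Plane spacing, um.
#' @param surface_index 1-based plane index of the specimen surface
#'   (planes 1..surface_index-1 lie above it, in the buffer).
#' @param photon_scale Stand-in for the excitation-times-instrument constant:
#'   expected photon count of a fully saturated voxel. Relevant when
#'   `poisson = TRUE`; all downstream analysis renormalizes it away.
#' @param background_fraction Background fluorescence as a fraction of the
#'   saturated level, in `[0, 1)` (e.g. 0.1 for GFP-labeled tissue).
#' @param gaussian_sigma Additive read-noise SD on the normalized scale.
#' @param poisson Apply Poisson shot noise at `photon_scale`?
#' @param mode `"homogeneous"` (uniform dye, e.g. FITC in resin) or
#'   `"fibers"` (sparse labeled structures).
#' @param fiber_count,fiber_radius,fiber_step_sd Fiber mode geometry: number
#'   of fibers, tube radius in pixels, and the SD (pixels/plane) of the
#'   lateral random-walk step of each fiber axis.
#' @param seed Integer RNG seed; fixes the series (and masks) exactly.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(params, times,
                           nx = 64, ny = 64, n_planes = 50,
                           z_step = 1, surface_index = 11,
                           photon_scale = 1, background_fraction = 0,
                           gaussian_sigma = 0, poisson = FALSE,
                           mode = c("homogeneous", "fibers"),
                           fiber_count = 10, fiber_radius = 1.5,
                           fiber_step_sd = 0.5,
                           seed = 1L) {
  params <- as_penetration_params(params)
  mode <- match.arg(mode)
  if (length(times) < 1L || any(times < 0) || is.unsorted(times, strictly = TRUE))
    stop_input("`times` must be non-negative and strictly increasing")
  if (nx < 1 || ny < 1 || n_planes < 1)
    stop_input("stack extents must be >= 1")
  if (surface_index < 1 || surface_index > n_planes)
    stop_input("`surface_index` must be a valid plane index")
  if (z_step <= 0) stop_input("`z_step` must be > 0")
  if (photon_scale <= 0) stop_input("`photon_scale` must be > 0")
  if (background_fraction < 0 || background_fraction >= 1)
    stop_input("`background_fraction` must lie in [0, 1)")
  if (gaussian_sigma < 0) stop_input("`gaussian_sigma` must be >= 0")
  if (mode == "fibers" && (fiber_count < 1 || fiber_radius <= 0))
    stop_input("fiber mode needs `fiber_count` >= 1 and `fiber_radius` > 0")
  structure(
    list(params = params, times = as.numeric(times),
         nx = as.integer(nx), ny = as.integer(ny),
         n_planes = as.integer(n_planes), z_step = z_step,
         surface_index = as.integer(surface_index),
         photon_scale = photon_scale,
         background_fraction = background_fraction,
         gaussian_sigma = gaussian_sigma, poisson = isTRUE(poisson),
         mode = mode, fiber_count = as.integer(fiber_count),
         fiber_radius = fiber_radius, fiber_step_sd = fiber_step_sd,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

# run `expr` with a private, deterministically seeded RNG stream, restoring
# the caller's RNG state afterwards
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate the fiber masks of a synthetic spec
#'
#' Each fiber is a random-walk polyline through the below-surface planes
#' (one axis point per plane, lateral steps Gaussian with SD
#' `fiber_step_sd`), dilated to a tube of radius `fiber_radius` pixels.
#' Masks are deterministic under the spec's seed and are shared by all time
#' points of a series.
#'
#' @param spec A [synthetic_spec()] in `"fibers"` mode.
#' @return A list of logical arrays `(n_planes, ny, nx)`, one per fiber.
#' @export
generate_fiber_masks <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$mode != "fibers") stop_input("spec is not in fiber mode")
  with_seed(spec$seed, {
    lapply(seq_len(spec$fiber_count), function(i) {
      m <- array(FALSE, dim = c(spec$n_planes, spec$ny, spec$nx))
      cy <- stats::runif(1, 1, spec$ny)
      cx <- stats::runif(1, 1, spec$nx)
      yy <- matrix(seq_len(spec$ny), spec$ny, spec$nx)
      xx <- matrix(seq_len(spec$nx), spec$ny, spec$nx, byrow = TRUE)
      for (p in spec$surface_index:spec$n_planes) {
        disk <- (yy - cy)^2 + (xx - cx)^2 <= spec$fiber_radius^2
        if (!any(disk)) {  # axis wandered outside: clamp back to the nearest edge
          cy <- min(max(cy, 1), spec$ny); cx <- min(max(cx, 1), spec$nx)
          disk <- (yy - cy)^2 + (xx - cx)^2 <= spec$fiber_radius^2
        }
        m[p, , ][disk] <- TRUE
        cy <- min(max(cy + stats::rnorm(1, 0, spec$fiber_step_sd), 1), spec$ny)
        cx <- min(max(cx + stats::rnorm(1, 0, spec$fiber_step_sd), 1), spec$nx)
      }
      m
    })
  })
}

#' Generate one synthetic 3-D stack
#'
#' Realizes the forward model at one time point of the spec, applying
#' Poisson and/or Gaussian noise as configured. The RNG stream is derived
#' from the spec seed and the time index, so any single stack of a series
#' can be regenerated independently and identically.
#'
#' @param spec A [synthetic_spec()].
#' @param t_index 1-based index into `spec$times`.
#' @param masks Fiber masks (from [generate_fiber_masks()]); required in
#'   fiber mode, ignored otherwise.
#' @return A 3-D numeric array `(n_planes, ny, nx)` of intensities on the
#'   `photon_scale` scale.
#' @export
generate_stack <- function(spec, t_index, masks = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  t_index <- as.integer(t_index)
  if (t_index < 1L || t_index > length(spec$times))
    stop_input("`t_index` out of range")
  t <- spec$times[t_index]
  depth <- (seq_len(spec$n_planes) - spec$surface_index) * spec$z_step
  f <- numeric(spec$n_planes)
  above <- depth < 0
  f[above] <- 1  # buffer above the block face reads as fully reactivated
  f[!above] <- fluorescence(spec$params, t, depth[!above])
  bg <- spec$background_fraction
  stack <- array(rep(f, times = spec$ny * spec$nx),
                 dim = c(spec$n_planes, spec$ny, spec$nx))
  if (spec$mode == "fibers") {
    if (is.null(masks)) stop_input("fiber mode requires `masks`")
    sig <- array(FALSE, dim = dim(stack))
    for (m in masks) sig <- sig | m
    sig[above, , ] <- TRUE  # buffer region is not structured
    stack <- stack * sig
  }
  mean_img <- spec$photon_scale * (bg + (1 - bg) * stack)
  with_seed(spec$seed * 1000L + t_index, {
    out <- mean_img
    if (spec$poisson)
      out <- array(stats::rpois(length(out), out), dim = dim(out))
    if (spec$gaussian_sigma > 0)
      out <- out + stats::rnorm(length(out),
                                sd = spec$gaussian_sigma * spec$photon_scale)
    out
  })
}

#' Generate a full synthetic stack series
#'
#' Shared geometry (and fiber masks, in fiber mode) across all time points;
#' entirely deterministic under the spec's seed.
#'
#' @param spec A [synthetic_spec()] with at least two times.
#' @return A list with elements `series` (a [stack_series()]), `masks`
#'   (fiber masks or `NULL`), and `spec`.
#' @export
generate_series <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (length(spec$times) < 2L)
    stop_input("a series needs at least 2 time points")
  masks <- if (spec$mode == "fibers") generate_fiber_masks(spec) else NULL
  stacks <- lapply(seq_along(spec$times), function(i)
    generate_stack(spec, i, masks = masks))
  list(
    series = stack_series(stacks, spec$times, spec$z_step, spec$surface_index),
    masks = masks,
    spec = spec
  )
}

#' Preset synthetic specs mirroring the two characterized samples
#'
#' `"standard"`: homogeneous FITC-in-resin slab, 1 um z step, 50 planes with
#' 10 above the surface, times 50/150/300/650 s, truth `D = 0.138`,
#' `K = 2.233`, no background. `"gfp"`: fiber-structured HM20-embedded
#' brain-like sample, 0.5 um z step, 50 planes, times 60/300/1200/1900 s,
#' truth `D = 0.026`, `K = 1.404`, background fraction 0.1.
#'
#' @param preset `"standard"` or `"gfp"`.
#' @param gaussian_sigma Normalized read-noise SD (default 0.02).
#' @param seed RNG seed.
#' @param ... Overrides passed on to [synthetic_spec()].
#' @return A [synthetic_spec()].
#' @export
synthetic_preset <- function(preset = c("standard", "gfp"),
                             gaussian_sigma = 0.02, seed = 1L, ...) {
  preset <- match.arg(preset)
  base <- if (preset == "standard") {
    list(params = penetration_params(0.138, 2.233, "synthetic FITC standard"),
         times = c(50, 150, 300, 650),
         nx = 64, ny = 64, n_planes = 50, z_step = 1, surface_index = 11)
  } else {
    list(params = penetration_params(0.026, 1.404, "synthetic HM20 GFP brain"),
         times = c(60, 300, 1200, 1900),
         nx = 64, ny = 64, n_planes = 50, z_step = 0.5, surface_index = 11,
         background_fraction = 0.1, mode = "fibers")
  }
  base$gaussian_sigma <- gaussian_sigma
  base$seed <- seed
  do.call(synthetic_spec, utils::modifyList(base, list(...)))
}
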