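#' Write and read a stack series as multi-page TIFF plus JSON sidecar
#'
#' One 32-bit float TIFF per time point (page order = z, top of stack first)
#' and a single `series.json` sidecar holding times, z step, surface plane
#' and the intensity calibration. TIFF storage is confined to `[0, 1]`, so
#' the series is mapped through a common affine transform (offset = series
#' minimum, scale = series range, both recorded in the sidecar) on write and
#' inverted on read. Downstream analysis is invariant to this rescaling.
#'
#' @param series A [stack_series()].
#' @param dir Output directory (created if needed).
#' @param basename Stem for the TIFF file names.
#' @return `write_stack_series()` returns the sidecar path invisibly;
#'   `read_stack_series()` returns a [stack_series()].
#' @export
write_stack_series <- function(series, dir, basename = "stack") {
  stopifnot(inherits(series, "stack_series"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  offset <- min(vapply(series$stacks, min, numeric(1)))
  scale <- max(1e-12, max(vapply(series$stacks, max, numeric(1))) - offset)
  files <- character(length(series$times))
  for (i in seq_along(series$times)) {
    st <- (series$stacks[[i]] - offset) / scale
    pages <- lapply(seq_len(dim(st)[1]), function(p) st[p, , ])
    files[i] <- sprintf("%s_t%03d.tif", basename, i)
    tiff::writeTIFF(pages, file.path(dir, files[i]), bits.per.sample = 32L)
  }
  sidecar <- list(
    format = "crpen-stack-series", version = 1L,
    times_s = series$times, z_step_um = series$z_step,
    surface_index = series$surface_index,
    intensity_scale = scale, intensity_offset = offset, files = files
  )
  path <- file.path(dir, "series.json")
  jsonlite::write_json(sidecar, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_stack_series
#' @export
read_stack_series <- function(dir) {
  path <- file.path(dir, "series.json")
  if (!file.exists(path)) stop_input(paste("no series.json sidecar in", dir))
  meta <- jsonlite::read_json(path, simplifyVector = TRUE)
  stacks <- lapply(meta$files, function(f) {
    pages <- tiff::readTIFF(file.path(dir, f), all = TRUE)
    arr <- array(0, dim = c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
    for (p in seq_along(pages)) arr[p, , ] <- pages[[p]]
    off <- if (is.null(meta$intensity_offset)) 0 else meta$intensity_offset
    arr * meta$intensity_scale + off
  })
  stack_series(stacks, meta$times_s, meta$z_step_um, meta$surface_index)
}

#' Write and read fiber masks as multi-page label TIFFs
#'
#' All fibers are stored in one label image (page order = z): voxel value
#' `i / n_fibers` encodes membership in fiber `i`, 0 is unlabeled.
#' Overlapping fibers keep the higher label.
#'
#' @param masks List of logical 3-D arrays.
#' @param path TIFF file path.
#' @return `write_fiber_masks()` returns `path` invisibly;
#'   `read_fiber_masks()` returns the list of logical arrays.
#' @export
write_fiber_masks <- function(masks, path) {
  if (!is.list(masks) || length(masks) == 0L)
    stop_input("`masks` must be a non-empty list")
  n <- length(masks)
  lab <- array(0, dim = dim(masks[[1]]))
  for (i in seq_len(n)) lab[masks[[i]]] <- i / n
  pages <- lapply(seq_len(dim(lab)[1]), function(p) lab[p, , ])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}

#' @rdname write_fiber_masks
#' @param n_fibers Number of fibers encoded in the label image.
#' @export
read_fiber_masks <- function(path, n_fibers) {
  pages <- tiff::readTIFF(path, all = TRUE)
  lab <- array(0, dim = c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (p in seq_along(pages)) lab[p, , ] <- pages[[p]]
  idx <- round(lab * n_fibers)
  lapply(seq_len(n_fibers), function(i) idx == i)
}

#' CSV dialects for profiles, contours and thickness curves
#'
#' Depth profiles travel as `time_s,depth_um,intensity`; contour series as
#' `level,time_s,depth_um`; CR-thickness curves as `time_s,level,depth_um`.
#'
#' @param profiles List of [depth_profile()] objects.
#' @param path CSV file path.
#' @return The write functions return `path` invisibly; the read functions
#'   return the corresponding objects.
#' @export
write_profiles_csv <- function(profiles, path) {
  df <- do.call(rbind, lapply(profiles, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_profiles_csv
#' @param normalized Mark the profiles read back as normalized?
#' @export
read_profiles_csv <- function(path, normalized = TRUE) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "depth_um", "intensity") %in% names(df)))
    stop_input("profile CSV must have columns time_s,depth_um,intensity")
  lapply(split(df, df$time_s), function(d) {
    d <- d[order(d$depth_um), ]
    depth_profile(d$time_s[1], d$depth_um, d$intensity, normalized = normalized)
  })
}

#' @rdname write_profiles_csv
#' @param contours List of [iso_contour_series()] objects.
#' @export
write_contours_csv <- function(contours, path) {
  df <- do.call(rbind, lapply(contours, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_profiles_csv
#' @export
read_contours_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("level", "time_s", "depth_um") %in% names(df)))
    stop_input("contour CSV must have columns level,time_s,depth_um")
  lapply(split(df, df$level), function(d) {
    d <- d[order(d$time_s), ]
    iso_contour_series(d$level[1], d$time_s, d$depth_um)
  })
}

#' @rdname write_profiles_csv
#' @param curves Data frame from [cr_thickness_curves()].
#' @export
write_curves_csv <- function(curves, path) {
  utils::write.csv(curves[, c("time_s", "level", "depth_um")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
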