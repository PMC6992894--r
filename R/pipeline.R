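#' Pipeline configuration
#'
#' All pipeline commands take a single configuration list, optionally read
#' from a YAML or JSON file, with sensible defaults: contour levels
#' `c(0.5, 0.9)`, zero background, seed 1. Unknown fields are carried along
#' untouched so presets can add their own.
#'
#' @param config A named list, or the path of a YAML/JSON config file.
#' @param ... Individual overrides applied on top of the file/list values.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list(), ...) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop_input(paste("config file not found:", config))
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  if (!is.list(config)) stop_input("`config` must be a list or a file path")
  defaults <- list(levels = c(0.5, 0.9), background = 0,
                   background_relative = TRUE, seed = 1L, preset = "standard")
  cfg <- utils::modifyList(defaults, config)
  cfg <- utils::modifyList(cfg, list(...))
  lv <- cfg$levels
  if (length(lv) < 1L || anyDuplicated(lv) || any(lv <= 0) || any(lv >= 1))
    stop_input("`levels` must be distinct values in (0, 1)")
  structure(cfg, class = c("pipeline_config", "list"))
}

manifest_path <- function(dir) file.path(dir, "manifest.json")

write_manifest <- function(dir, cfg, extra = list()) {
  files <- setdiff(list.files(dir), "manifest.json")
  checksums <- as.list(tools::md5sum(file.path(dir, files)))
  names(checksums) <- files
  man <- c(list(
    package = "crpen",
    version = as.character(utils::packageVersion("crpen")),
    config = unclass(cfg),
    files_md5 = checksums
  ), extra)
  jsonlite::write_json(man, manifest_path(dir), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest_path(dir))
}

#' Simulate a synthetic stack series to disk
#'
#' Builds the synthetic spec from the config (fields: `preset`, `seed`,
#' `gaussian_sigma`, plus any [synthetic_spec()] override such as `times`,
#' `nx`, `background_fraction`), generates the series, and writes TIFFs, the
#' JSON sidecar, fiber masks (fiber mode) and a manifest with per-file MD5
#' checksums into `out`.
#'
#' @param config A [pipeline_config()] (or list / file path coercible to one).
#' @param out Output directory.
#' @return The manifest path, invisibly.
#' @export
cmd_simulate <- function(config = list(), out) {
  cfg <- pipeline_config(config)
  overrides <- cfg[setdiff(intersect(names(cfg), names(formals(synthetic_spec))),
                           c("params", "seed", "gaussian_sigma"))]
  args <- c(list(preset = cfg$preset, seed = cfg$seed), overrides)
  if (!is.null(cfg$gaussian_sigma)) args$gaussian_sigma <- cfg$gaussian_sigma
  spec <- do.call(synthetic_preset, args)
  gen <- generate_series(spec)
  write_stack_series(gen$series, out)
  if (!is.null(gen$masks))
    write_fiber_masks(gen$masks, file.path(out, "fiber_masks.tif"))
  write_manifest(out, cfg, list(
    mode = spec$mode, n_fibers = if (is.null(gen$masks)) 0L else length(gen$masks),
    truth = list(D_um2_per_s = spec$params$D, K = spec$params$K)))
}

#' Extract normalized depth profiles from a stack series on disk
#'
#' Reads the TIFF + sidecar series in `input`, computes per-time profiles
#' (fiber-masked when a `fiber_masks.tif` and manifest are present, plain
#' xy means otherwise), normalizes them with the configured background, and
#' writes `profiles.csv` to `out`.
#'
#' @inheritParams cmd_simulate
#' @param input Directory holding the series (from [cmd_simulate()] or
#'   equivalent).
#' @return Invisibly, the list of normalized profiles.
#' @export
cmd_extract <- function(config = list(), input, out = input) {
  cfg <- pipeline_config(config)
  series <- read_stack_series(input)
  masks <- NULL
  mask_file <- file.path(input, "fiber_masks.tif")
  if (file.exists(mask_file) && file.exists(manifest_path(input))) {
    man <- jsonlite::read_json(manifest_path(input), simplifyVector = TRUE)
    if (!is.null(man$n_fibers) && man$n_fibers > 0)
      masks <- read_fiber_masks(mask_file, man$n_fibers)
  }
  profiles <- lapply(seq_along(series$times), function(i) {
    raw <- if (is.null(masks)) mean_profile(series, i)
           else masked_profile(series, i, masks)
    normalize_profile(raw, background = cfg$background,
                      relative = cfg$background_relative)
  })
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  write_profiles_csv(profiles, file.path(out, "profiles.csv"))
  invisible(profiles)
}

#' Fit penetration parameters from stacks, profiles or contours on disk
#'
#' Accepts, in order of preference, a contour CSV (`contours.csv`), a
#' profile CSV (`profiles.csv`), or a stack-series directory (which is first
#' run through [cmd_extract()]). Writes the fit report JSON to `out`.
#'
#' @inheritParams cmd_extract
#' @param input A directory or a CSV file path.
#' @param out Output JSON path.
#' @return The `fit_report`, invisibly.
#' @export
cmd_fit <- function(config = list(), input, out) {
  cfg <- pipeline_config(config)
  report <- NULL
  if (file.exists(input) && !dir.exists(input)) {
    header <- names(utils::read.csv(input, nrows = 1))
    if ("level" %in% header) {
      contours <- read_contours_csv(input)
      contours <- contours[match(cfg$levels, vapply(contours, `[[`, 0, "level"))]
      if (any(vapply(contours, is.null, logical(1))))
        stop_input("configured levels not present in the contour CSV")
      report <- fit_penetration_from_contours(contours, sample = cfg$sample)
    } else {
      profiles <- read_profiles_csv(input)
      report <- fit_penetration(profiles, levels = cfg$levels, sample = cfg$sample)
    }
  } else if (dir.exists(input)) {
    if (file.exists(file.path(input, "profiles.csv"))) {
      profiles <- read_profiles_csv(file.path(input, "profiles.csv"))
    } else {
      profiles <- cmd_extract(cfg, input)
    }
    report <- fit_penetration(profiles, levels = cfg$levels, sample = cfg$sample)
  } else {
    stop_input(paste("input not found:", input))
  }
  dir.create(dirname(out), recursive = TRUE, showWarnings = FALSE)
  write_fit_report_json(report, out)
  invisible(report)
}

#' Predict CR-thickness curves for given parameters
#'
#' Forward model only: writes a `time_s,level,depth_um` CSV of
#' `Z_level(time)` for the configured levels and time grid. `params` may be
#' a [penetration_params()], a params JSON path, or a sample name from
#' [resin_params()].
#'
#' @inheritParams cmd_simulate
#' @param params Parameters (object, JSON path, or resin sample name /
#'   substring such as `"GMA"`).
#' @param times Time grid, s (default 1..3600 s in 1 s steps).
#' @param out Output CSV path.
#' @return The curve data.frame, invisibly.
#' @export
cmd_predict <- function(config = list(), params, times = seq(1, 3600), out) {
  cfg <- pipeline_config(config)
  if (is.character(params) && length(params) == 1L) {
    if (file.exists(params)) {
      params <- read_params_json(params)
    } else {
      tab <- resin_params()
      hit <- grep(params, tab$sample, ignore.case = TRUE)
      if (length(hit) != 1L)
        stop_input(paste("cannot resolve parameter source:", params))
      params <- penetration_params(tab$D_um2_per_s[hit], tab$K[hit],
                                   tab$sample[hit])
    }
  }
  params <- as_penetration_params(params)
  curves <- cr_thickness_curves(params, levels = cfg$levels, times = times)
  dir.create(dirname(out), recursive = TRUE, showWarnings = FALSE)
  write_curves_csv(curves, out)
  invisible(curves)
}

#' Verify fitted parameters against measured profiles
#'
#' Computes the per-time determination coefficient of the forward model
#' against each normalized profile in `input` (a `profiles.csv` or a
#' directory containing one) and writes them as JSON.
#'
#' @inheritParams cmd_predict
#' @param input Profile CSV path or directory.
#' @param out Output JSON path.
#' @return Named numeric vector of R^2 values, invisibly.
#' @export
cmd_verify <- function(config = list(), params, input, out) {
  cfg <- pipeline_config(config)
  if (is.character(params)) params <- read_params_json(params)
  params <- as_penetration_params(params)
  path <- if (dir.exists(input)) file.path(input, "profiles.csv") else input
  if (!file.exists(path)) stop_input(paste("profiles not found:", path))
  profiles <- read_profiles_csv(path)
  r2 <- vapply(profiles, function(p) profile_r_squared(params, p), numeric(1))
  names(r2) <- vapply(profiles, function(p) format(p$time), character(1))
  dir.create(dirname(out), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(params = list(D_um2_per_s = params$D, K = params$K),
         profile_r_squared = as.list(r2)),
    out, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(r2)
}
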