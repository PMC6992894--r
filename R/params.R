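#' Penetration model parameters
#'
#' Bundle the two parameters of the buffer-penetration model: the diffusion
#' coefficient `D` of hydroxyl ions through the resin micropores and the
#' dimensionless saturation coefficient `K` mapping normalized ion
#' concentration to the fluorescent (dianion) state. Fluorescence saturates
#' wherever the normalized concentration exceeds `1/K`.
#'
#' Units are fixed throughout the package: depth in micrometres, time in
#' seconds, hence `D` in um^2/s.
#'
#' @param D Diffusion coefficient, um^2/s. Must be > 0.
#' @param K Saturation coefficient, dimensionless. Must be >= 1; `K = 1`
#'   disables saturation so fluorescence equals concentration.
#' @param sample Optional sample label carried through reports.
#' @return An object of class `penetration_params`.
#' @examples
#' penetration_params(D = 0.138, K = 2.233, sample = "FITC/GMA standard")
#' @export
penetration_params <- function(D, K = 1, sample = NULL) {
  if (!is.numeric(D) || length(D) != 1L || !is.finite(D) || D <= 0)
    stop_parameter("`D` must be a single finite number > 0 (um^2/s)")
  if (!is.numeric(K) || length(K) != 1L || !is.finite(K) || K < 1)
    stop_parameter("`K` must be a single finite number >= 1")
  structure(
    list(D = as.numeric(D), K = as.numeric(K), sample = sample),
    class = "penetration_params"
  )
}

#' @export
print.penetration_params <- function(x, ...) {
  cat("Penetration model parameters")
  if (!is.null(x$sample)) cat(" [", x$sample, "]", sep = "")
  cat("\n  D = ", format(x$D), " um^2/s", sep = "")
  cat("\n  K = ", format(x$K),
      "   (saturation threshold 1/K = ", format(signif(1 / x$K, 4)), ")\n",
      sep = "")
  invisible(x)
}

as_penetration_params <- function(x) {
  if (inherits(x, "penetration_params")) return(x)
  if (is.list(x) && !is.null(x$D))
    return(penetration_params(x$D, if (is.null(x$K)) 1 else x$K, x$sample))
  stop_parameter("cannot interpret object as penetration parameters")
}

#' Derived model constants
#'
#' The two constants that appear in the sample-specific closed form of the
#' fluorescence distribution: `2*sqrt(D)`, the depth scale of the erfc
#' argument (um per sqrt-second), and `1/K`, the normalized concentration
#' above which fluorescence is saturated.
#'
#' @param params A [penetration_params()] object.
#' @return A list with elements `two_sqrt_D` and `inv_K`.
#' @examples
#' derived_constants(penetration_params(D = 0.138, K = 2.233))
#' @export
derived_constants <- function(params) {
  params <- as_penetration_params(params)
  list(two_sqrt_D = 2 * sqrt(params$D), inv_K = 1 / params$K)
}

#' Read and write penetration parameters as JSON
#'
#' Parameters are stored as `{"D_um2_per_s": ..., "K": ..., "sample": ...}`.
#'
#' @param params A [penetration_params()] object.
#' @param path File path.
#' @return `write_params_json()` returns `path` invisibly;
#'   `read_params_json()` returns a [penetration_params()] object.
#' @export
write_params_json <- function(params, path) {
  params <- as_penetration_params(params)
  jsonlite::write_json(
    list(D_um2_per_s = params$D, K = params$K,
         sample = if (is.null(params$sample)) NA_character_ else params$sample),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path) {
  x <- jsonlite::read_json(path)
  sample <- x$sample
  if (is.null(sample) || (length(sample) == 1L && is.na(sample))) sample <- NULL
  penetration_params(x$D_um2_per_s, x$K, sample)
}

#' Published resin penetration coefficients
#'
#' Fitted `(D, K)` pairs for Thy1-EGFP mouse brain embedded in three common
#' resins, ordered by penetration rate. GMA (hydrophilic, non-cross-linking)
#' penetrates fastest, LR white (hydrophilic, cross-linking) is intermediate,
#' and Lowicryl HM20 (hydrophobic, cross-linking) is slowest.
#'
#' @return A data.frame with columns `sample`, `D_um2_per_s`, `K`.
#' @examples
#' resin_params()
#' @export
resin_params <- function() {
  data.frame(
    sample = c("GMA resin-embedded mouse brain",
               "LR white resin-embedded mouse brain",
               "HM20 resin-embedded mouse brain"),
    D_um2_per_s = c(0.332, 0.156, 0.026),
    K = c(2.227, 1.635, 1.404),
    stringsAsFactors = FALSE
  )
}
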