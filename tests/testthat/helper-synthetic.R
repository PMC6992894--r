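# small fixture factories shared across test files

std_params <- function() penetration_params(0.138, 2.233)
gfp_params <- function() penetration_params(0.026, 1.404)

# compact homogeneous spec: 8x8 lateral, 30 planes (5 above the surface),
# standard-sample times and truth parameters unless overridden
tiny_spec <- function(...) {
  args <- utils::modifyList(
    list(params = std_params(), times = c(50, 150, 300, 650),
         nx = 8, ny = 8, n_planes = 30, z_step = 1, surface_index = 6,
         gaussian_sigma = 0, seed = 1L),
    list(...))
  do.call(synthetic_spec, args)
}

# normalized profiles straight from a generated series
extract_profiles <- function(gen, background = 0) {
  lapply(seq_along(gen$series$times), function(i) {
    raw <- if (is.null(gen$masks)) mean_profile(gen$series, i)
           else masked_profile(gen$series, i, gen$masks)
    normalize_profile(raw, background = background)
  })
}
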