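#' @keywords internal
#' @noRd
crpen_stop <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "crpen_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

# error taxonomy used across the package:
#   crpen_domain_error     — argument outside the model's domain (t<0, level>1, ...)
#   crpen_parameter_error  — invalid model parameters (D<=0, K<1, unstable step)
#   crpen_input_error      — malformed data inputs (empty stack, bad mask, ordering)
#   crpen_degenerate_profile_error — profile has no resolvable plateau
#   crpen_not_penetrated_error     — contour level not yet crossed at this time
#   crpen_insufficient_data_error  — too few usable points for a fit
#   crpen_no_solution_error        — two-level system has no bracketed root
#   crpen_inconsistent_data_error  — solution violates K >= 1

stop_domain <- function(msg) crpen_stop(msg, "crpen_domain_error")
stop_parameter <- function(msg) crpen_stop(msg, "crpen_parameter_error")
stop_input <- function(msg) crpen_stop(msg, "crpen_input_error")
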