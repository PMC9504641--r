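#' Thermal energy k_B * T
#'
#' Boltzmann constant times absolute temperature, in the piconewton-nanometre
#' units used throughout the force-spectroscopy module
#' (4.1145 pN nm at 298 K).
#'
#' @param temperature Absolute temperature in kelvin.
#' @return Thermal energy in pN nm.
#' @examples
#' thermal_energy(298)
#' @export
thermal_energy <- function(temperature = 298) {
  if (!is.numeric(temperature) || any(!is.finite(temperature)) ||
      any(temperature <= 0)) {
    stop("`temperature` must be a positive finite number (K)", call. = FALSE)
  }
  4.1145 * temperature / 298
}

# internal: scalar positivity check with a readable message
check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive finite number", name),
         call. = FALSE)
  }
  invisible(x)
}
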