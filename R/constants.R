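# Boltzmann constant, exact (SI definition).
.kb_J <- 1.380649e-23
# Same constant in pN nm / K: 1 J = 1e12 pN * 1e9 nm = 1e21 pN nm.
.kb_pN_nm <- .kb_J * 1e21

#' Physical constants for thermal-fluctuation analyses
#'
#' Bundles the Boltzmann constant (fixed at its exact SI value) with the bath
#' temperature used to convert observed deformation variance into elastic
#' moduli via equipartition.
#'
#' @param temperature Bath temperature in kelvin. Default 300 K, the standard
#'   simulation thermostat setting for nucleosome systems.
#'
#' @return A list with elements `k_b` (J/K) and `T` (K).
#' @examples
#' physical_constants()$T
#' @export
physical_constants <- function(temperature = 300) {
  stopifnot(is.numeric(temperature), length(temperature) == 1L)
  if (!is.finite(temperature) || temperature <= 0) {
    abort("`temperature` must be a positive, finite number of kelvin.")
  }
  list(k_b = .kb_J, T = temperature)
}

# Thermal energy in pN nm at temperature T (K).
.kbT_pN_nm <- function(temperature) .kb_pN_nm * temperature
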