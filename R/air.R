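#' Physical properties of the in-process air
#'
#' Bundles the gas properties entering the suction-pressure model: the
#' temperature, ambient pressure, molar mass, dynamic viscosity and density of
#' the air above and inside the die, plus the universal gas constant. Defaults
#' are standard ambient values; the density defaults to the ideal-gas value
#' `patm * M / (R * T)`, which makes the Darcy/ideal-gas lumped constant
#' collapse to `K * patm / (eta * L)` (see [model_constant()]).
#'
#' @param temperature Absolute temperature, K.
#' @param ambient_pressure Ambient (atmospheric) pressure, Pa.
#' @param molar_mass Average molar mass of air, kg/mol.
#' @param dynamic_viscosity Dynamic viscosity of air, Pa s.
#' @param gas_constant Universal gas constant, J/(mol K).
#' @param density Air density, kg/m^3. `NULL` (default) uses the ideal-gas
#'   value. A supplied value must agree with the ideal-gas value within 1%.
#'
#' @return An object of class `air_properties`.
#' @export
#' @examples
#' air <- air_properties()
#' air$density # ~1.20 kg/m^3
air_properties <- function(temperature = 293.15,
                           ambient_pressure = 101325,
                           molar_mass = 0.02896,
                           dynamic_viscosity = 1.8e-5,
                           gas_constant = 8.314,
                           density = NULL) {
  stopifnot(
    temperature > 0, ambient_pressure > 0, molar_mass > 0,
    dynamic_viscosity > 0, gas_constant > 0
  )
  rho_ideal <- ambient_pressure * molar_mass / (gas_constant * temperature)
  if (is.null(density)) {
    density <- rho_ideal
  } else {
    stopifnot(density > 0)
    if (abs(density - rho_ideal) / rho_ideal > 0.01) {
      stop("air density is inconsistent with the ideal-gas law (>1% off ",
           signif(rho_ideal, 4), " kg/m^3)", call. = FALSE)
    }
  }
  structure(
    list(
      temperature = temperature,
      ambient_pressure = ambient_pressure,
      molar_mass = molar_mass,
      dynamic_viscosity = dynamic_viscosity,
      gas_constant = gas_constant,
      density = density
    ),
    class = "air_properties"
  )
}

#' @export
print.air_properties <- function(x, ...) {
  cat("Air properties:\n")
  cat(sprintf("  T = %.2f K, patm = %g Pa, M = %g kg/mol\n",
              x$temperature, x$ambient_pressure, x$molar_mass))
  cat(sprintf("  eta = %g Pa s, rho = %.4g kg/m^3, R = %g J/(mol K)\n",
              x$dynamic_viscosity, x$density, x$gas_constant))
  invisible(x)
}
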