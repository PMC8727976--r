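#' Gas properties for hydraulic calculations
#'
#' Thermophysical properties of the ventilated gas mixture. Defaults describe
#' the 80% oxygen / 20% dry air blend used for the reference simulations:
#' specific gas constant 265 J kg^-1 K^-1, specific heat capacity
#' 936 J kg^-1 K^-1, kinematic viscosity 2.02e-5 m^2 s^-1, at standard ambient
#' pressure and 293 K. Density is derived from the ideal-gas law.
#'
#' @param specific_gas_constant Specific gas constant R (J kg^-1 K^-1).
#' @param specific_heat_capacity Specific heat capacity c_p (J kg^-1 K^-1).
#' @param kinematic_viscosity Kinematic viscosity nu (m^2 s^-1).
#' @param ambient_pressure Absolute ambient pressure (Pa).
#' @param ambient_temperature Ambient temperature (K).
#'
#' @return An object of class `gas_properties`: a named list of the five
#'   fields plus the derived `density` (kg m^-3).
#' @examples
#' gas <- gas_properties()
#' gas$density # about 1.30 kg/m^3
#' @export
gas_properties <- function(specific_gas_constant = 265,
                           specific_heat_capacity = 936,
                           kinematic_viscosity = 2.02e-5,
                           ambient_pressure = 101325,
                           ambient_temperature = 293) {
  check_number(specific_gas_constant, "specific_gas_constant", 0, strict_lower = TRUE)
  check_number(specific_heat_capacity, "specific_heat_capacity", 0, strict_lower = TRUE)
  check_number(kinematic_viscosity, "kinematic_viscosity", 0, strict_lower = TRUE)
  check_number(ambient_pressure, "ambient_pressure", 0, strict_lower = TRUE)
  check_number(ambient_temperature, "ambient_temperature", 0, strict_lower = TRUE)
  density <- ambient_pressure / (specific_gas_constant * ambient_temperature)
  structure(
    list(
      specific_gas_constant = specific_gas_constant,
      specific_heat_capacity = specific_heat_capacity,
      kinematic_viscosity = kinematic_viscosity,
      ambient_pressure = ambient_pressure,
      ambient_temperature = ambient_temperature,
      density = density
    ),
    class = "gas_properties"
  )
}

#' @export
print.gas_properties <- function(x, ...) {
  cat("<gas_properties>\n")
  cat(sprintf("  R = %g J/kg/K, c_p = %g J/kg/K\n",
              x$specific_gas_constant, x$specific_heat_capacity))
  cat(sprintf("  nu = %g m^2/s, p_amb = %g Pa, T = %g K, rho = %.4f kg/m^3\n",
              x$kinematic_viscosity, x$ambient_pressure,
              x$ambient_temperature, x$density))
  invisible(x)
}
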