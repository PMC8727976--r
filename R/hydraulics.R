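#' Pipe Reynolds number of a restrictor throat
#'
#' Re = U_bar D / nu = 4 V / (pi D nu) for bulk velocity U_bar, bore diameter
#' D and volumetric flow V. The reference bench tests operate restrictors at
#' Re of roughly 5000-8000, i.e. fully turbulent.
#'
#' @param flow Volumetric flow rate (L/min), >= 0. Vectorised.
#' @param diameter Bore diameter (mm), > 0.
#' @param gas A [gas_properties()] object (kinematic viscosity is used).
#' @return Dimensionless Reynolds number(s); 0 at zero flow.
#' @examples
#' reynolds_number(6.6, 2, gas_properties()) # about 3467
#' @export
reynolds_number <- function(flow, diameter, gas = gas_properties()) {
  if (!is.numeric(diameter) || any(diameter <= 0)) {
    stop_domain("`diameter` must be positive")
  }
  if (any(flow < 0)) stop_domain("`flow` must be non-negative")
  q <- flow * M3S_PER_LMIN
  d <- diameter * M_PER_MM
  4 * q / (pi * d * gas$kinematic_viscosity)
}

#' Ideal orifice pressure drop
#'
#' The incompressible orifice relation
#' dp = 8 rho V^2 / (pi^2 c_D^2 D^4), evaluated in SI and returned in cmH2O.
#' The discharge coefficient c_D (typically 0.6-1) absorbs vena-contracta and
#' shape effects. The relation is extended antisymmetrically to negative flow
#' (dp(-V) = -dp(V)) so the orifice can only dissipate energy.
#'
#' @param flow Volumetric flow rate (L/min). Vectorised; may be signed.
#' @param diameter Bore diameter (mm), > 0.
#' @param discharge_coefficient c_D in (0, 1].
#' @param gas A [gas_properties()] object (density is used).
#' @return Pressure drop (cmH2O), odd in `flow`.
#' @examples
#' orifice_pressure_drop(6.6, 2, 0.8) # about 12.7 cmH2O
#' @export
orifice_pressure_drop <- function(flow, diameter, discharge_coefficient,
                                  gas = gas_properties()) {
  if (!is.numeric(diameter) || any(diameter <= 0)) {
    stop_domain("`diameter` must be positive")
  }
  if (discharge_coefficient <= 0 || discharge_coefficient > 1) {
    stop_domain("`discharge_coefficient` must be in (0, 1]")
  }
  q <- flow * M3S_PER_LMIN
  d <- diameter * M_PER_MM
  dp_pa <- 8 * gas$density * q * abs(q) /
    (pi^2 * discharge_coefficient^2 * d^4)
  dp_pa * CMH2O_PER_PA
}

#' Quadratic restrictor pressure drop
#'
#' Evaluates the signed quadratic law dp = a V |V| + b V (cmH2O, V in L/min).
#' For positive flow this is the usual a V^2 + b V; the signed form makes the
#' law odd in flow, so flow reversal cannot produce an unphysical energy gain.
#'
#' @param law A [restrictor_law()].
#' @param flow Volumetric flow rate (L/min). Vectorised; may be signed.
#' @return Pressure drop (cmH2O).
#' @examples
#' quadratic_pressure_drop(reference_law(4), 20.4) # 7.40 cmH2O
#' @export
quadratic_pressure_drop <- function(law, flow) {
  stopifnot(inherits(law, "restrictor_law"))
  law$a * flow * abs(flow) + law$b * flow
}

#' Pressure drop from the cross-diameter power-law model
#'
#' Evaluates dp = k_a D^m_a V^2 + k_b D^m_b V (signed in V), the power-law
#' generalisation of the per-diameter quadratic laws. The reference model
#' (dp ~ 3.55 D^-4.03 V^2 + 10.27 D^-3.46 V) is valid for bores of 2-4 mm and
#' flows up to 60 L/min; outside 2-4 mm a warning is raised but the value is
#' still returned.
#'
#' @param diameter Bore diameter (mm), > 0.
#' @param flow Volumetric flow rate (L/min). Vectorised; may be signed.
#' @param model A [powerlaw_model()]; defaults to the reference model.
#' @return Pressure drop (cmH2O).
#' @examples
#' powerlaw_pressure_drop(3, 14) # about 11.5 cmH2O
#' @export
powerlaw_pressure_drop <- function(diameter, flow,
                                   model = reference_powerlaw_model()) {
  stopifnot(inherits(model, "powerlaw_model"))
  if (!is.numeric(diameter) || any(diameter <= 0)) {
    stop_domain("`diameter` must be positive")
  }
  if (any(diameter < 2) || any(diameter > 4)) {
    warning("power-law model evaluated outside its 2-4 mm validity range",
            call. = FALSE)
  }
  model$k_a * diameter^model$m_a * flow * abs(flow) +
    model$k_b * diameter^model$m_b * flow
}

#' Fourth-power diameter sensitivity of orifice pressure drop
#'
#' At fixed flow and discharge coefficient, orifice pressure drop scales as
#' D^-4, so an undersized print multiplies dp by (nominal / true)^4. A part
#' printed at 1.69 mm instead of 2.00 mm therefore produces roughly twice the
#' design pressure drop.
#'
#' @param nominal_diameter Design bore diameter (mm), > 0.
#' @param true_diameter As-printed bore diameter (mm), > 0. Vectorised.
#' @return The multiplicative pressure-drop factor (nominal/true)^4.
#' @examples
#' diameter_sensitivity(2.00, 1.69) # about 1.96
#' @export
diameter_sensitivity <- function(nominal_diameter, true_diameter) {
  if (any(nominal_diameter <= 0) || any(true_diameter <= 0)) {
    stop_domain("diameters must be positive")
  }
  (nominal_diameter / true_diameter)^4
}

#' Equivalent mean (secant) resistance of a restrictor law
#'
#' Because the pressure drop is quadratic in flow, the instantaneous
#' resistance varies over the breath; the secant resistance dp/V at a
#' representative flow, converted to the clinical unit cmH2O/(L/s), summarises
#' it: R_mean = 60 (a V + b) with V in L/min. At V -> 0 this is 60 b.
#'
#' @param law A [restrictor_law()].
#' @param flow Representative (e.g. time-average inspiratory) flow (L/min),
#'   >= 0. Vectorised.
#' @return Resistance in cmH2O (L/s)^-1.
#' @examples
#' mean_resistance(reference_law(NA), 30) # 0.2166, the bare splitter
#' @export
mean_resistance <- function(law, flow) {
  stopifnot(inherits(law, "restrictor_law"))
  if (any(flow < 0)) stop_domain("`flow` must be non-negative")
  60 * (law$a * flow + law$b)
}
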