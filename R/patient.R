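#' Patient airway and lung parameters
#'
#' Lumped mechanical properties of one patient: respiratory-system compliance
#' and inspiratory/expiratory airway resistance. Only inspiration is
#' simulated; the expiratory resistance is carried for completeness.
#' Literature-typical defaults: R_insp 13, R_exp 12 cmH2O/(L/s).
#'
#' @param compliance Respiratory compliance C (L/cmH2O), > 0.
#' @param resistance_inspiration Inspiratory airway resistance (cmH2O/(L/s)).
#' @param resistance_expiration Expiratory airway resistance (cmH2O/(L/s)).
#' @return An object of class `patient_params`.
#' @export
patient_params <- function(compliance,
                           resistance_inspiration = 13,
                           resistance_expiration = 12) {
  check_number(compliance, "compliance", 0, strict_lower = TRUE)
  check_number(resistance_inspiration, "resistance_inspiration", 0)
  check_number(resistance_expiration, "resistance_expiration", 0)
  structure(
    list(compliance = compliance,
         resistance_inspiration = resistance_inspiration,
         resistance_expiration = resistance_expiration),
    class = "patient_params"
  )
}

#' Breathing-circuit parameters
#'
#' Compliance and resistance of the endotracheal tube plus breathing-circuit
#' tubing between the splitter port and the patient. Defaults: C_bc 0.004
#' L/cmH2O, R_bc 22 cmH2O/(L/s).
#'
#' @param compliance_bc Circuit compliance (L/cmH2O), >= 0.
#' @param resistance_bc Circuit resistance (cmH2O/(L/s)), >= 0.
#' @return An object of class `circuit_params`.
#' @export
circuit_params <- function(compliance_bc = 0.004, resistance_bc = 22) {
  check_number(compliance_bc, "compliance_bc", 0)
  check_number(resistance_bc, "resistance_bc", 0)
  structure(
    list(compliance_bc = compliance_bc, resistance_bc = resistance_bc),
    class = "circuit_params"
  )
}

#' RC time constant of the patient + circuit network
#'
#' tau = R C + R_bc (C_bc + C), using the inspiratory airway resistance.
#' This is the characteristic filling time of the single-compartment model.
#'
#' @param patient A [patient_params()] object.
#' @param circuit A [circuit_params()] object.
#' @return Time constant (s).
#' @examples
#' time_constant(patient_params(0.1), circuit_params()) # 3.588 s
#' @export
time_constant <- function(patient, circuit = circuit_params()) {
  patient$resistance_inspiration * patient$compliance +
    circuit$resistance_bc * (circuit$compliance_bc + patient$compliance)
}

#' Instantaneous inspiratory flow of the RC model
#'
#' The single-compartment balance p0 = (tau/C) dV/dt + V/C solved for dV/dt:
#' flow = (p0 - V/C) C / tau.
#'
#' @param p0 Driving stagnation pressure at the circuit inlet (cmH2O).
#' @param volume Inspired volume above end-expiratory equilibrium (L).
#' @param patient A [patient_params()] object.
#' @param circuit A [circuit_params()] object.
#' @return Flow dV/dt (L/s).
#' @export
inspiratory_flow_rate <- function(p0, volume, patient,
                                  circuit = circuit_params()) {
  tau <- time_constant(patient, circuit)
  if (tau <= 0) {
    stop_domain("degenerate model: time constant is zero (instantaneous equilibration)")
  }
  (p0 - volume / patient$compliance) * patient$compliance / tau
}

#' Closed-form volume response to a pressure step
#'
#' Analytic solution of the linear RC model under a constant driving pressure:
#' V(t) = C p0 + (v0 - C p0) exp(-t / tau). Serves as the exact oracle for
#' the numerical branch integrator when no restrictor is present.
#'
#' @param p0_step Constant driving pressure above PEEP (cmH2O).
#' @param t Time(s) since the step (s), >= 0. Vectorised.
#' @param patient A [patient_params()] object.
#' @param circuit A [circuit_params()] object.
#' @param v0 Initial volume (L).
#' @return Volume(s) (L).
#' @examples
#' p <- patient_params(0.2)
#' step_response_volume(25, 1.25, p) # about 0.808 L
#' @export
step_response_volume <- function(p0_step, t, patient,
                                 circuit = circuit_params(), v0 = 0) {
  if (any(t < 0)) stop_domain("`t` must be non-negative")
  tau <- time_constant(patient, circuit)
  v_inf <- patient$compliance * p0_step
  v_inf + (v0 - v_inf) * exp(-t / tau)
}

#' Convert stagnation to static pressure at a circular port
#'
#' Bernoulli's relation p0 = p + rho U^2 / 2 with bulk velocity
#' U = V / (pi (d/2)^2). At the 22 mm splitter ports the dynamic term is
#' negligible (~0.01 cmH2O); inside a 2 mm restrictor throat it reaches
#' several cmH2O.
#'
#' @param p0 Stagnation pressure (cmH2O).
#' @param flow Volumetric flow (L/min). Vectorised.
#' @param port_diameter Port internal diameter (mm), > 0.
#' @param gas A [gas_properties()] object.
#' @return Static pressure (cmH2O).
#' @export
stagnation_to_static <- function(p0, flow, port_diameter,
                                 gas = gas_properties()) {
  if (any(port_diameter <= 0)) stop_domain("`port_diameter` must be positive")
  area <- pi * (port_diameter * M_PER_MM / 2)^2
  u <- flow * M3S_PER_LMIN / area
  p0 - 0.5 * gas$density * u^2 * CMH2O_PER_PA
}
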