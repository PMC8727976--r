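# Reference differential-ventilation scenario: 4 mm restrictor on the
# compliant-lung port, bare port for the stiff lung.
ventilator:
  peak_pressure_cmH2O: 30
  peep_cmH2O: 5
  respiratory_rate_per_min: 16
  pressure_max_time_s: 1.25
  rise_time_s: 0.0
  target_end_inspiratory_volume_L: 0.48
gas:
  specific_gas_constant_J_per_kgK: 265
  specific_heat_capacity_J_per_kgK: 936
  kinematic_viscosity_m2_per_s: 2.02e-5
  ambient_pressure_Pa: 101325
  ambient_temperature_K: 293
patients:
  - label: restricted
    compliance_L_per_cmH2O: 0.1
    resistance_insp_cmH2O_per_Ls: 13
    resistance_exp_cmH2O_per_Ls: 12
  - label: unrestricted
    compliance_L_per_cmH2O: 0.2
    resistance_insp_cmH2O_per_Ls: 13
    resistance_exp_cmH2O_per_Ls: 12
circuit:
  compliance_bc_L_per_cmH2O: 0.004
  resistance_bc_cmH2O_per_Ls: 22
restrictors:
  restricted: 4
  unrestricted: none
solver:
  dt_s: 0.001
  tol_Ls: 1.0e-9
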