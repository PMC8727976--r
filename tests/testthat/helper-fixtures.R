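# Shared fixtures built in code.

# coarse solver options keep unit tests fast; acceptance uses the 1 ms default
fast_opts <- function(dt = 0.005) solver_opts(dt = dt)

step_waveform <- function(pip = 30, peep = 5, t_max = 1.25, dt = 0.005) {
  build_waveform(
    ventilator_settings(peak_pressure = pip, peep = peep,
                        pressure_max_time = t_max, rise_time = 0),
    dt = dt
  )
}

# quadratic law consistent with the reference power-law model at diameter d,
# used as a synthetic "true" part of known hydraulic diameter
law_at_diameter <- function(d, model = reference_powerlaw_model()) {
  restrictor_law(diameter = d,
                 a = model$k_a * d^model$m_a,
                 b = model$k_b * d^model$m_b)
}

ref_laws <- function() {
  tab <- reference_coefficients()
  stats::setNames(
    lapply(seq_len(nrow(tab)), function(i) {
      restrictor_law(diameter = tab$diameter[i], a = tab$a[i], b = tab$b[i])
    }),
    c("2", "3", "4", "none")
  )
}
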