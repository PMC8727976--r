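#' Pressure-control ventilator settings
#'
#' Parameters of the parametric inspiratory pressure waveform used to drive
#' the simulation: baseline at PEEP, an optional exponential rise to the peak
#' inspiratory pressure, then a hold at the peak for `pressure_max_time`.
#' Defaults are the reference pressure-control settings: PIP 30 cmH2O, PEEP
#' 5 cmH2O, 16 breaths/min, pressure-maximum time 1.25 s, target
#' end-inspiratory volume 0.480 L per patient. `rise_time = 0` gives a pure
#' step, for which the closed-form RC response applies exactly.
#'
#' @param peak_pressure Peak inspiratory pressure, PIP (cmH2O).
#' @param peep Positive end-expiratory pressure (cmH2O), >= 0 and < PIP.
#' @param respiratory_rate Breaths per minute; the inspiratory window must fit
#'   inside one breath period.
#' @param pressure_max_time Hold time at PIP (s), > 0.
#' @param rise_time Duration of the exponential approach to PIP (s), >= 0.
#'   The rise uses time constant `rise_time / 3`, reaching 95% of the
#'   PIP-PEEP span at `t = rise_time`.
#' @param target_end_inspiratory_volume Target delivered volume per patient
#'   (L), used by the titration tools.
#' @return An object of class `ventilator_settings`.
#' @export
ventilator_settings <- function(peak_pressure = 30,
                                peep = 5,
                                respiratory_rate = 16,
                                pressure_max_time = 1.25,
                                rise_time = 0,
                                target_end_inspiratory_volume = 0.480) {
  check_number(peak_pressure, "peak_pressure", 0, strict_lower = TRUE)
  check_number(peep, "peep", 0)
  check_number(respiratory_rate, "respiratory_rate", 0, strict_lower = TRUE)
  check_number(pressure_max_time, "pressure_max_time", 0, strict_lower = TRUE)
  check_number(rise_time, "rise_time", 0)
  check_number(target_end_inspiratory_volume, "target_end_inspiratory_volume",
               0, strict_lower = TRUE)
  if (peak_pressure <= peep) {
    stop_config("peak_pressure", "must exceed `peep`")
  }
  if (pressure_max_time + rise_time >= 60 / respiratory_rate) {
    stop_config("pressure_max_time",
                "inspiratory window (rise_time + pressure_max_time) must be shorter than one breath period")
  }
  structure(
    list(peak_pressure = peak_pressure, peep = peep,
         respiratory_rate = respiratory_rate,
         pressure_max_time = pressure_max_time, rise_time = rise_time,
         target_end_inspiratory_volume = target_end_inspiratory_volume),
    class = "ventilator_settings"
  )
}

#' Build the sampled inspiratory pressure waveform
#'
#' Samples the parametric pressure-control waveform on a uniform grid over the
#' inspiratory window `[0, rise_time + pressure_max_time]`. With
#' `rise_time = 0` the waveform is a step: already at PIP at t = 0. With a
#' positive rise time it follows
#' `PEEP + (PIP - PEEP) (1 - exp(-3 t / rise_time))` up to `rise_time`, then
#' holds at PIP. Expiration is out of scope; the waveform ends at
#' end-inspiration.
#'
#' @param settings A [ventilator_settings()] object.
#' @param dt Sample interval (s); must satisfy `0 < dt < pressure_max_time/10`.
#' @return A `pressure_waveform`: a tibble with columns `time_s` and
#'   `pressure_cmH2O`, carrying the generating settings as attribute
#'   `settings`.
#' @examples
#' w <- build_waveform(ventilator_settings(), dt = 0.01)
#' range(w$pressure_cmH2O) # 30 everywhere: default rise_time is 0
#' @export
build_waveform <- function(settings, dt = 0.001) {
  stopifnot(inherits(settings, "ventilator_settings"))
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0 ||
      dt >= settings$pressure_max_time / 10) {
    stop_config("dt", "must satisfy 0 < dt < pressure_max_time / 10")
  }
  t_end <- settings$rise_time + settings$pressure_max_time
  times <- seq(0, t_end, by = dt)
  if (times[length(times)] < t_end - 1e-12) times <- c(times, t_end)
  p <- waveform_pressure(times, settings)
  structure(
    tibble::tibble(time_s = times, pressure_cmH2O = p),
    settings = settings,
    class = c("pressure_waveform", class(tibble::tibble()))
  )
}

# closed-form waveform; exact evaluator behind build_waveform and the solver
#' @keywords internal
waveform_pressure <- function(t, settings) {
  pip <- settings$peak_pressure
  peep <- settings$peep
  rise <- settings$rise_time
  if (rise <= 0) {
    return(rep(pip, length(t)))
  }
  # the rise expression applies through t = rise (95% of the span); the
  # hold pins the plateau at PIP strictly afterwards
  ifelse(
    t <= rise,
    peep + (pip - peep) * (1 - exp(-3 * t / rise)),
    pip
  )
}

#' Sample a waveform at arbitrary instants
#'
#' Linear interpolation between the stored samples; exact at sample points.
#'
#' @param waveform A `pressure_waveform` from [build_waveform()].
#' @param t Instant(s) within the waveform's time range (s). Vectorised.
#' @return Pressure(s) in cmH2O.
#' @export
sample_pressure <- function(waveform, t) {
  stopifnot(inherits(waveform, "pressure_waveform"))
  tmin <- waveform$time_s[1]
  tmax <- waveform$time_s[nrow(waveform)]
  if (any(t < tmin - 1e-12) || any(t > tmax + 1e-12)) {
    stop_domain("`t` outside waveform range [%g, %g] s", tmin, tmax)
  }
  stats::approx(waveform$time_s, waveform$pressure_cmH2O, xout = t,
                rule = 2)$y
}

#' Write a waveform to CSV
#'
#' Two columns, `time_s` and `pressure_cmH2O`, with a header row.
#'
#' @param waveform A `pressure_waveform`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_waveform_csv <- function(waveform, path) {
  readr::write_csv(tibble::as_tibble(waveform), path)
  invisible(path)
}
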