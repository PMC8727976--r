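#' End-inspiratory volume vs inspiratory time
#'
#' Sweeps the inspiratory window and records the end-inspiratory (tidal)
#' volume delivered to one branch, the desk-scale analogue of repeating the
#' simulation for increasing inspiratory times and cumulatively integrating
#' the delivered volume. For each grid time `T`, the ventilator waveform is
#' rebuilt so that the whole inspiratory window (rise + hold) equals `T`, the
#' scenario is simulated, and the final volume recorded.
#'
#' @param scenario A [scenario()] object.
#' @param branch Label of the branch to titrate (e.g. `"restricted"`).
#' @param t_grid Increasing grid of inspiratory times (s); default 12 points
#'   from 0.25 s to 5 s, the conventional sweep range.
#' @return A `titration_curve`: a tibble with columns `inspiratory_time_s`
#'   and `end_volume_L`, carrying the scenario and branch as attributes.
#' @examples
#' sc <- default_scenario()
#' tc <- titration_curve(sc, "restricted", t_grid = c(0.5, 1, 2))
#' @export
titration_curve <- function(scenario, branch,
                            t_grid = seq(0.25, 5, length.out = 12)) {
  stopifnot(inherits(scenario, "ventsplitr_scenario"))
  if (is.unsorted(t_grid, strictly = TRUE)) {
    stop_config("t_grid", "must be strictly increasing")
  }
  vols <- purrr::map_dbl(t_grid, function(T) {
    end_volume_at_time(scenario, branch, T)
  })
  structure(
    tibble::tibble(inspiratory_time_s = t_grid, end_volume_L = vols),
    branch = branch,
    scenario = scenario,
    class = c("titration_curve", class(tibble::tibble()))
  )
}

# Simulate one branch with the inspiratory window set to T and return the
# end-inspiratory volume. T covers rise + hold; T must exceed the rise time.
#' @keywords internal
end_volume_at_time <- function(scenario, branch, T) {
  if (T <= 0) return(0)
  s <- scenario$ventilator
  if (T <= s$rise_time) {
    stop_config("t_grid", sprintf(
      "inspiratory time %g s does not exceed the rise time %g s", T,
      s$rise_time))
  }
  settings <- ventilator_settings(
    peak_pressure = s$peak_pressure, peep = s$peep,
    # slow the nominal rate if needed so long windows stay valid
    respiratory_rate = min(s$respiratory_rate, 0.99 * 60 / T),
    pressure_max_time = T - s$rise_time,
    rise_time = s$rise_time,
    target_end_inspiratory_volume = s$target_end_inspiratory_volume
  )
  w <- build_waveform(settings, dt = min(scenario$solver$dt,
                                         settings$pressure_max_time / 20))
  cfg <- scenario_branch(scenario, branch)
  opts <- scenario$solver
  opts$dt <- min(opts$dt, settings$pressure_max_time / 20)
  res <- if (is.null(scenario$common_law)) {
    simulate_branch(w, cfg, scenario$gas, opts)
  } else {
    other <- setdiff(names(scenario$branches), branch)
    out <- simulate_splitter(w, scenario$branches[c(branch, other)],
                             scenario$gas, opts,
                             common_law = scenario$common_law)
    out$branches[[branch]]
  }
  attr(res, "end_inspiratory_volume")
}

#' Inspiratory time required to reach a target volume
#'
#' Inverts the (monotone) titration relation by bisection: the smallest
#' inspiratory time `T` at which the branch's end-inspiratory volume reaches
#' `target_volume`, to a tolerance of 1 ms. Smaller restrictor bores need
#' longer inspiratory times for the same delivered volume.
#'
#' @param scenario A [scenario()] object.
#' @param branch Branch label.
#' @param target_volume Target end-inspiratory volume (L), > 0. Defaults to
#'   the ventilator settings' target.
#' @param t_max Upper bound of the search (s); default 5 s.
#' @return Required inspiratory time (s).
#' @examples
#' sc <- default_scenario()
#' required_inspiratory_time(sc, "unrestricted", 0.3)
#' @export
required_inspiratory_time <- function(scenario, branch,
                                      target_volume =
                                        scenario$ventilator$target_end_inspiratory_volume,
                                      t_max = 5) {
  stopifnot(inherits(scenario, "ventsplitr_scenario"))
  check_number(target_volume, "target_volume", 0, strict_lower = TRUE)
  v_max <- end_volume_at_time(scenario, branch, t_max)
  if (v_max < target_volume) {
    cfg <- scenario_branch(scenario, branch)
    asym <- cfg$patient$compliance *
      (scenario$ventilator$peak_pressure - scenario$ventilator$peep)
    rlang::abort(
      sprintf(paste0(
        "target volume %.3f L unreachable within %.2f s for branch '%s' ",
        "(volume at t_max %.3f L; asymptotic volume C * dP = %.3f L)"),
        target_volume, t_max, branch, v_max, asym),
      class = "ventsplitr_unreachable_target",
      asymptotic_volume = asym
    )
  }
  lo <- max(1e-3, scenario$ventilator$rise_time + 1e-3)
  hi <- t_max
  if (end_volume_at_time(scenario, branch, lo) >= target_volume) return(lo)
  while (hi - lo > 1e-3) {
    mid <- (lo + hi) / 2
    if (end_volume_at_time(scenario, branch, mid) >= target_volume) {
      hi <- mid
    } else {
      lo <- mid
    }
  }
  hi
}
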