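#' Configuration of one splitter branch
#'
#' Bundles the patient, breathing circuit and restrictor law attached to one
#' port of the Y-splitter. An [identity_law()] restrictor means an
#' unrestricted port.
#'
#' @param label Non-empty branch label, unique within a scenario
#'   (e.g. `"restricted"`, `"unrestricted"`).
#' @param patient A [patient_params()] object.
#' @param circuit A [circuit_params()] object.
#' @param restrictor A [restrictor_law()]; defaults to the identity law.
#' @return An object of class `branch_config`.
#' @export
branch_config <- function(label, patient, circuit = circuit_params(),
                          restrictor = identity_law()) {
  if (!is.character(label) || length(label) != 1L || !nzchar(label)) {
    stop_config("label", "must be a non-empty string")
  }
  stopifnot(inherits(patient, "patient_params"),
            inherits(circuit, "circuit_params"),
            inherits(restrictor, "restrictor_law"))
  structure(
    list(label = label, patient = patient, circuit = circuit,
         restrictor = restrictor),
    class = "branch_config"
  )
}

#' Solver options for the branch integrator
#'
#' @param dt Integration time step (s); default 1 ms.
#' @param tol Convergence tolerance on the per-step flow update (L/s).
#' @param max_iter Maximum Newton iterations per step.
#' @return A list of class `solver_opts`.
#' @export
solver_opts <- function(dt = 0.001, tol = 1e-9, max_iter = 60L) {
  check_number(dt, "dt", 0, strict_lower = TRUE)
  check_number(tol, "tol", 0, strict_lower = TRUE)
  structure(list(dt = dt, tol = tol, max_iter = as.integer(max_iter)),
            class = "solver_opts")
}

# Safeguarded Newton with a maintained bisection bracket for a scalar,
# monotonically increasing residual g. Returns the root.
#' @keywords internal
solve_flow <- function(g, dg, tol, max_iter, q_init = 0, t_at = NA_real_) {
  # establish a sign-changing bracket by doubling outwards
  lo <- min(q_init, 0) - 1e-3
  hi <- max(q_init, 0) + 1e-3
  expand <- 0L
  while (g(lo) > 0 && expand < 80L) {
    lo <- lo * 2 - 1
    expand <- expand + 1L
  }
  expand <- 0L
  while (g(hi) < 0 && expand < 80L) {
    hi <- hi * 2 + 1
    expand <- expand + 1L
  }
  glo <- g(lo); ghi <- g(hi)
  if (glo > 0 || ghi < 0) {
    stop_domain("flow solve: could not bracket a root at t = %g s", t_at)
  }
  q <- if (q_init > lo && q_init < hi) q_init else (lo + hi) / 2
  for (i in seq_len(max_iter)) {
    gi <- g(q)
    if (gi > 0) hi <- q else lo <- q
    d <- dg(q)
    q_new <- if (is.finite(d) && d > 0) q - gi / d else NA_real_
    if (!is.finite(q_new) || q_new <= lo || q_new >= hi) {
      q_new <- (lo + hi) / 2 # bisection fallback
    }
    if (abs(q_new - q) < tol && abs(g(q_new)) < 1e-8) {
      return(q_new)
    }
    q <- q_new
  }
  rlang::abort(
    sprintf("flow solver did not converge at t = %g s (residual %.3e)",
            t_at, g(q)),
    class = "ventsplitr_solver_error"
  )
}

# One implicit-trapezoidal step for a single branch: given the node driving
# pressure p_drive (above PEEP) at t_{k+1}, the previous flow q_k (L/s) and
# volume v_k (L), solve for q_{k+1} such that the trapezoidal volume update
# and the branch balance (tau/C) q + V/C + dp(q) = p_drive hold together.
#' @keywords internal
branch_step <- function(p_drive, q_prev, v_prev, dt, tau, comp, law,
                        opts, t_at) {
  a <- law$a; b <- law$b
  base <- tau / comp + dt / (2 * comp)
  vpart <- (v_prev + dt / 2 * q_prev) / comp
  g <- function(q) {
    vdot <- 60 * q
    base * q + vpart + a * vdot * abs(vdot) + b * vdot - p_drive
  }
  dg <- function(q) {
    base + 60 * (2 * a * abs(60 * q) + b)
  }
  solve_flow(g, dg, opts$tol, opts$max_iter, q_init = q_prev, t_at = t_at)
}

# initial flow at t = 0 (no trapezoidal term): (tau/C) q + v0/C + dp(q) = p
#' @keywords internal
branch_flow_at <- function(p_drive, v, tau, comp, law, opts, t_at) {
  a <- law$a; b <- law$b
  g <- function(q) {
    vdot <- 60 * q
    tau / comp * q + v / comp + a * vdot * abs(vdot) + b * vdot - p_drive
  }
  dg <- function(q) tau / comp + 60 * (2 * a * abs(60 * q) + b)
  solve_flow(g, dg, opts$tol, opts$max_iter, q_init = 0, t_at = t_at)
}

#' Simulate inspiration into one splitter branch
#'
#' Integrates the coupled restrictor + RC-patient balance
#' `p_vent(t) - dp_restrictor(V') = (tau/C) V' + V/C`
#' over the inspiratory window, with driving pressures referenced to PEEP and
#' initial volume zero (volume is measured above the end-expiratory
#' equilibrium). At each implicit-trapezoidal step the scalar monotone
#' equation for the flow is solved by safeguarded Newton iteration with a
#' bisection fallback.
#'
#' @param waveform A `pressure_waveform` from [build_waveform()].
#' @param branch A [branch_config()].
#' @param gas A [gas_properties()] object (reserved for stagnation/static
#'   conversions in reporting; the lumped balance itself is in cmH2O).
#' @param opts A [solver_opts()] list.
#' @return A `branch_result`: a tibble with columns `time_s`,
#'   `port_pressure_cmH2O` (stagnation at the splitter outlet),
#'   `flow_Lmin`, `volume_L` and `restrictor_drop_cmH2O`, with summary
#'   attributes `peak_pressure_drop`, `peak_flow`, `end_inspiratory_volume`
#'   and `label`. Use [glance()] for a one-row summary.
#' @examples
#' w <- build_waveform(ventilator_settings(), dt = 0.01)
#' br <- branch_config("restricted", patient_params(0.1),
#'                     restrictor = reference_law(4))
#' res <- simulate_branch(w, br, opts = solver_opts(dt = 0.01))
#' glance(res)
#' @export
simulate_branch <- function(waveform, branch, gas = gas_properties(),
                            opts = solver_opts()) {
  stopifnot(inherits(waveform, "pressure_waveform"),
            inherits(branch, "branch_config"))
  settings <- attr(waveform, "settings")
  peep <- if (!is.null(settings)) settings$peep else waveform$pressure_cmH2O[1]
  t_end <- waveform$time_s[nrow(waveform)]
  times <- seq(0, t_end, by = opts$dt)
  if (times[length(times)] < t_end - 1e-12) times <- c(times, t_end)
  p_vent <- sample_pressure(waveform, times)
  drive <- p_vent - peep

  comp <- branch$patient$compliance
  tau <- time_constant(branch$patient, branch$circuit)
  if (tau <= 0) {
    stop_domain("degenerate model: time constant is zero for branch '%s'",
                branch$label)
  }
  law <- branch$restrictor

  n <- length(times)
  q <- numeric(n)  # L/s
  v <- numeric(n)  # L
  q[1] <- branch_flow_at(drive[1], 0, tau, comp, law, opts, times[1])
  for (k in seq_len(n - 1L)) {
    dt_k <- times[k + 1L] - times[k]
    q[k + 1L] <- branch_step(drive[k + 1L], q[k], v[k], dt_k, tau, comp,
                             law, opts, times[k + 1L])
    v[k + 1L] <- v[k] + dt_k / 2 * (q[k] + q[k + 1L])
  }

  flows <- 60 * q
  drops <- quadratic_pressure_drop(law, flows)
  new_branch_result(
    tibble::tibble(
      time_s = times,
      port_pressure_cmH2O = p_vent,
      flow_Lmin = flows,
      volume_L = v,
      restrictor_drop_cmH2O = drops
    ),
    label = branch$label,
    diameter = law$diameter,
    settings = settings
  )
}

#' @keywords internal
new_branch_result <- function(data, label, diameter, settings) {
  structure(
    data,
    label = label,
    diameter = diameter,
    settings = settings,
    peak_pressure_drop = max(data$restrictor_drop_cmH2O),
    peak_flow = max(data$flow_Lmin),
    end_inspiratory_volume = data$volume_L[nrow(data)],
    class = c("branch_result", class(tibble::tibble()))
  )
}

#' Simulate a two-patient splitter
#'
#' Runs [simulate_branch()] for each of the two branches. The Y-splitter body
#' is lossless by default (its measured pressure loss is ~0.1 cmH2O, i.e.
#' negligible), so the branches decouple and each sees the full ventilator
#' pressure. An optional common series restrictor law couples the branches
#' through a shared upstream pressure drop on the total flow.
#'
#' @param waveform A `pressure_waveform`.
#' @param branches A list of exactly two [branch_config()] objects with
#'   distinct labels.
#' @param gas A [gas_properties()] object.
#' @param opts A [solver_opts()] list.
#' @param common_law Optional [restrictor_law()] applied to the summed branch
#'   flow upstream of the split; `NULL` (default) disables the coupling.
#' @return A `splitter_result`: a list with elements `branches` (named list
#'   of `branch_result`) and `summary` (a tibble with one row per branch:
#'   `branch`, `diameter_mm`, `peak_pressure_drop_cmH2O`, `peak_flow_Lmin`,
#'   `end_inspiratory_volume_L`).
#' @examples
#' w <- build_waveform(ventilator_settings(), dt = 0.01)
#' res <- simulate_splitter(w, list(
#'   branch_config("restricted", patient_params(0.1),
#'                 restrictor = reference_law(4)),
#'   branch_config("unrestricted", patient_params(0.2))
#' ), opts = solver_opts(dt = 0.01))
#' res$summary
#' @export
simulate_splitter <- function(waveform, branches, gas = gas_properties(),
                              opts = solver_opts(), common_law = NULL) {
  if (!is.list(branches) || length(branches) != 2L ||
      !all(vapply(branches, inherits, logical(1), "branch_config"))) {
    stop_config("branches", "must be a list of exactly two branch_config objects")
  }
  labels <- vapply(branches, `[[`, character(1), "label")
  if (anyDuplicated(labels)) {
    stop_config("branches", "branch labels must be distinct")
  }
  results <- if (is.null(common_law) ||
                 (common_law$a == 0 && common_law$b == 0)) {
    lapply(branches, function(b) simulate_branch(waveform, b, gas, opts))
  } else {
    simulate_coupled(waveform, branches, gas, opts, common_law)
  }
  names(results) <- labels
  summary <- purrr::map_dfr(results, function(r) {
    tibble::tibble(
      branch = attr(r, "label"),
      diameter_mm = attr(r, "diameter"),
      peak_pressure_drop_cmH2O = attr(r, "peak_pressure_drop"),
      peak_flow_Lmin = attr(r, "peak_flow"),
      end_inspiratory_volume_L = attr(r, "end_inspiratory_volume")
    )
  })
  structure(list(branches = results, summary = summary),
            class = "splitter_result")
}

# Coupled two-branch integration when a common series law is present.
# Outer bisection on total flow Q; inner scalar solves give each branch flow
# at the shared node pressure p_node = drive - dp_common(Q).
#' @keywords internal
simulate_coupled <- function(waveform, branches, gas, opts, common_law) {
  settings <- attr(waveform, "settings")
  peep <- if (!is.null(settings)) settings$peep else waveform$pressure_cmH2O[1]
  t_end <- waveform$time_s[nrow(waveform)]
  times <- seq(0, t_end, by = opts$dt)
  if (times[length(times)] < t_end - 1e-12) times <- c(times, t_end)
  p_vent <- sample_pressure(waveform, times)
  drive <- p_vent - peep
  n <- length(times)

  taus <- vapply(branches, function(b) time_constant(b$patient, b$circuit),
                 numeric(1))
  comps <- vapply(branches, function(b) b$patient$compliance, numeric(1))
  laws <- lapply(branches, `[[`, "restrictor")

  q <- matrix(0, n, 2)
  v <- matrix(0, n, 2)

  flows_at_node <- function(p_node, k, dt_k, initial) {
    vapply(1:2, function(i) {
      if (initial) {
        branch_flow_at(p_node, 0, taus[i], comps[i], laws[[i]], opts,
                       times[k])
      } else {
        branch_step(p_node, q[k - 1L, i], v[k - 1L, i], dt_k, taus[i],
                    comps[i], laws[[i]], opts, times[k])
      }
    }, numeric(1))
  }

  step_coupled <- function(k, dt_k, initial) {
    resid <- function(Q) {
      p_node <- drive[k] - quadratic_pressure_drop(common_law, 60 * Q)
      Q - sum(flows_at_node(p_node, k, dt_k, initial))
    }
    lo <- 0; hi <- 1
    while (resid(hi) < 0 && hi < 1e6) hi <- hi * 2
    if (resid(lo) > 0) lo <- -hi
    root <- stats::uniroot(resid, c(lo, hi), tol = opts$tol)$root
    p_node <- drive[k] - quadratic_pressure_drop(common_law, 60 * root)
    flows_at_node(p_node, k, dt_k, initial)
  }

  q[1, ] <- step_coupled(1L, NA_real_, initial = TRUE)
  for (k in 2:n) {
    dt_k <- times[k] - times[k - 1L]
    q[k, ] <- step_coupled(k, dt_k, initial = FALSE)
    v[k, ] <- v[k - 1L, ] + dt_k / 2 * (q[k - 1L, ] + q[k, ])
  }

  lapply(1:2, function(i) {
    flows <- 60 * q[, i]
    new_branch_result(
      tibble::tibble(
        time_s = times,
        port_pressure_cmH2O = p_vent -
          quadratic_pressure_drop(common_law, 60 * rowSums(q)),
        flow_Lmin = flows,
        volume_L = v[, i],
        restrictor_drop_cmH2O = quadratic_pressure_drop(laws[[i]], flows)
      ),
      label = branches[[i]]$label,
      diameter = laws[[i]]$diameter,
      settings = settings
    )
  })
}

#' @export
print.splitter_result <- function(x, ...) {
  cat("<splitter_result>\n")
  print(x$summary)
  invisible(x)
}
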