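#' Assemble a simulation scenario
#'
#' A scenario bundles everything one splitter simulation needs: ventilator
#' settings, gas properties, exactly two branch configurations and solver
#' options, plus an optional common series restrictor law.
#'
#' @param ventilator A [ventilator_settings()] object.
#' @param branches List of exactly two [branch_config()] objects with
#'   distinct labels.
#' @param gas A [gas_properties()] object.
#' @param solver A [solver_opts()] list.
#' @param common_law Optional [restrictor_law()] shared upstream of the split.
#' @return An object of class `ventsplitr_scenario`.
#' @export
scenario <- function(ventilator = ventilator_settings(),
                     branches,
                     gas = gas_properties(),
                     solver = solver_opts(),
                     common_law = NULL) {
  if (!is.list(branches) || length(branches) != 2L ||
      !all(vapply(branches, inherits, logical(1), "branch_config"))) {
    stop_config("branches", "must be a list of exactly two branch_config objects")
  }
  labels <- vapply(branches, `[[`, character(1), "label")
  if (anyDuplicated(labels)) {
    stop_config("branches", "branch labels must be distinct")
  }
  names(branches) <- labels
  structure(
    list(ventilator = ventilator, gas = gas, branches = branches,
         solver = solver, common_law = common_law),
    class = "ventsplitr_scenario"
  )
}

#' @keywords internal
scenario_branch <- function(scenario, label) {
  cfg <- scenario$branches[[label]]
  if (is.null(cfg)) {
    stop_config("branch", sprintf("no branch labelled '%s' (have: %s)",
                                  label,
                                  paste(names(scenario$branches),
                                        collapse = ", ")))
  }
  cfg
}

#' Default two-patient scenario
#'
#' The reference differential-ventilation setup: PIP 30 / PEEP 5 cmH2O,
#' 1.25 s pressure-maximum time; a compliant lung (C = 0.1 L/cmH2O) behind a
#' restricted port and a stiff lung (C = 0.2 L/cmH2O in the reference
#' summary; see the vignette on the compliance-labelling ambiguity) behind
#' the unrestricted port; airway R 13, circuit C_bc 0.004 / R_bc 22.
#'
#' @param restrictor_diameter Bore of the restricted port: 2, 3, 4 (mm) or
#'   `NA` for no restrictor.
#' @param compliance_restricted,compliance_unrestricted Branch compliances
#'   (L/cmH2O).
#' @return A [scenario()] object.
#' @examples
#' sc <- default_scenario(4)
#' @export
default_scenario <- function(restrictor_diameter = 4,
                             compliance_restricted = 0.1,
                             compliance_unrestricted = 0.2) {
  scenario(
    ventilator = ventilator_settings(),
    branches = list(
      branch_config("restricted",
                    patient_params(compliance_restricted),
                    circuit_params(),
                    reference_law(restrictor_diameter)),
      branch_config("unrestricted",
                    patient_params(compliance_unrestricted),
                    circuit_params(),
                    identity_law())
    )
  )
}

#' Simulate a scenario
#'
#' Builds the waveform from the scenario's ventilator settings and runs
#' [simulate_splitter()].
#'
#' @param scenario A [scenario()] object.
#' @return A `splitter_result`.
#' @export
simulate_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "ventsplitr_scenario"))
  w <- build_waveform(scenario$ventilator, dt = scenario$solver$dt)
  simulate_splitter(w, unname(scenario$branches), scenario$gas,
                    scenario$solver, common_law = scenario$common_law)
}

#' Read a scenario from a YAML config
#'
#' Expected layout (units embedded in key names):
#' ```yaml
#' ventilator:
#'   peak_pressure_cmH2O: 30
#'   peep_cmH2O: 5
#'   respiratory_rate_per_min: 16
#'   pressure_max_time_s: 1.25
#'   rise_time_s: 0.0
#'   target_end_inspiratory_volume_L: 0.48
#' gas: {}                      # optional overrides of gas_properties()
#' patients:
#'   - label: restricted
#'     compliance_L_per_cmH2O: 0.1
#'     resistance_insp_cmH2O_per_Ls: 13
#'   - label: unrestricted
#'     compliance_L_per_cmH2O: 0.2
#' circuit:
#'   compliance_bc_L_per_cmH2O: 0.004
#'   resistance_bc_cmH2O_per_Ls: 22
#' restrictors:
#'   restricted: 4              # reference bore (mm), "none", or {a: ..., b: ...}
#'   unrestricted: none
#' solver:
#'   dt_s: 0.001
#'   tol_Ls: 1.0e-9
#' ```
#'
#' @param path Path to the YAML file.
#' @return A [scenario()] object.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop_config("path", sprintf("no such file: %s", path))
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop_config("path", "config did not parse to a mapping")

  vraw <- cfg$ventilator %||% list()
  vent <- ventilator_settings(
    peak_pressure = vraw$peak_pressure_cmH2O %||% 30,
    peep = vraw$peep_cmH2O %||% 5,
    respiratory_rate = vraw$respiratory_rate_per_min %||% 16,
    pressure_max_time = vraw$pressure_max_time_s %||% 1.25,
    rise_time = vraw$rise_time_s %||% 0,
    target_end_inspiratory_volume =
      vraw$target_end_inspiratory_volume_L %||% 0.480
  )

  graw <- cfg$gas %||% list()
  gas <- gas_properties(
    specific_gas_constant = graw$specific_gas_constant_J_per_kgK %||% 265,
    specific_heat_capacity = graw$specific_heat_capacity_J_per_kgK %||% 936,
    kinematic_viscosity = graw$kinematic_viscosity_m2_per_s %||% 2.02e-5,
    ambient_pressure = graw$ambient_pressure_Pa %||% 101325,
    ambient_temperature = graw$ambient_temperature_K %||% 293
  )

  craw <- cfg$circuit %||% list()
  circuit <- circuit_params(
    compliance_bc = craw$compliance_bc_L_per_cmH2O %||% 0.004,
    resistance_bc = craw$resistance_bc_cmH2O_per_Ls %||% 22
  )

  if (is.null(cfg$patients) || length(cfg$patients) != 2L) {
    stop_config("patients", "config must list exactly two patients")
  }
  restr <- cfg$restrictors %||% list()
  branches <- lapply(cfg$patients, function(p) {
    if (is.null(p$label)) stop_config("patients", "each patient needs a label")
    law_spec <- restr[[p$label]]
    law <- parse_restrictor_spec(law_spec)
    branch_config(
      label = p$label,
      patient = patient_params(
        compliance = p$compliance_L_per_cmH2O,
        resistance_inspiration = p$resistance_insp_cmH2O_per_Ls %||% 13,
        resistance_expiration = p$resistance_exp_cmH2O_per_Ls %||% 12
      ),
      circuit = circuit,
      restrictor = law
    )
  })

  sraw <- cfg$solver %||% list()
  solver <- solver_opts(
    dt = sraw$dt_s %||% 0.001,
    tol = sraw$tol_Ls %||% 1e-9
  )

  scenario(ventilator = vent, branches = branches, gas = gas,
           solver = solver)
}

#' @keywords internal
parse_restrictor_spec <- function(x) {
  if (is.null(x)) return(identity_law())
  if (is.character(x) && identical(tolower(x), "none")) return(identity_law())
  if (is.numeric(x) && length(x) == 1L) return(reference_law(x))
  if (is.list(x)) {
    return(restrictor_law(
      diameter = x$diameter_mm %||% NA_real_,
      a = x$a_cmH2O_per_Lmin2 %||% x$a %||% 0,
      b = x$b_cmH2O_per_Lmin %||% x$b %||% 0
    ))
  }
  stop_config("restrictors", "entries must be a bore diameter, 'none', or {a, b}")
}

#' Run a scenario config end to end and write artifacts
#'
#' Reads the YAML scenario, simulates both branches, and writes one CSV time
#' series per branch, a JSON summary and a wide summary CSV (metric rows by
#' branch columns) into `out_dir`.
#'
#' @param path Path to the scenario YAML.
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a named list of written file paths.
#' @export
run_scenario <- function(path, out_dir) {
  sc <- read_scenario(path)
  res <- simulate_scenario(sc)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  paths <- list()
  for (lbl in names(res$branches)) {
    f <- file.path(out_dir, paste0("branch_", lbl, ".csv"))
    readr::write_csv(tibble::as_tibble(res$branches[[lbl]]), f)
    paths[[paste0("branch_", lbl)]] <- f
  }

  summary_json <- file.path(out_dir, "summary.json")
  js <- purrr::map(res$branches, function(r) {
    list(
      peak_drop_cmH2O = attr(r, "peak_pressure_drop"),
      peak_flow_Lmin = attr(r, "peak_flow"),
      end_inspiratory_volume_L = attr(r, "end_inspiratory_volume")
    )
  })
  jsonlite::write_json(js, summary_json, auto_unbox = TRUE, digits = NA)
  paths$summary_json <- summary_json

  summary_csv <- file.path(out_dir, "summary_table.csv")
  readr::write_csv(summary_wide(res$summary), summary_csv)
  paths$summary_csv <- summary_csv
  invisible(paths)
}

# wide layout: one row per metric, one column per branch
#' @keywords internal
summary_wide <- function(summary) {
  summary |>
    tidyr::pivot_longer(-c("branch", "diameter_mm"),
                        names_to = "metric", values_to = "value") |>
    dplyr::select("metric", "branch", "value") |>
    tidyr::pivot_wider(names_from = "branch", values_from = "value")
}
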