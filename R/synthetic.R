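#' Bench instrument noise model
#'
#' Multiplicative Gaussian measurement noise at percent-of-reading instrument
#' accuracies: 0.6% (1 SD) for the mass flow meter and 0.5% for the pressure
#' transducers, the stated accuracies of the reference bench rig. Accuracy
#' percentages are read as 1-SD relative Gaussian noise, the conventional
#' simulation interpretation of a transducer accuracy spec.
#'
#' @param flow_relative_sd Relative SD of flow readings; default 0.006.
#' @param pressure_relative_sd Relative SD of pressure readings; default
#'   0.005.
#' @param seed Integer RNG seed; generators are pure functions of
#'   (parameters, seed).
#' @return An object of class `bench_noise`.
#' @export
bench_noise <- function(flow_relative_sd = 0.006,
                        pressure_relative_sd = 0.005,
                        seed = 1L) {
  check_number(flow_relative_sd, "flow_relative_sd", 0)
  check_number(pressure_relative_sd, "pressure_relative_sd", 0)
  structure(
    list(flow_relative_sd = flow_relative_sd,
         pressure_relative_sd = pressure_relative_sd,
         seed = as.integer(seed)),
    class = "bench_noise"
  )
}

#' Generate synthetic bench pressure-flow measurements
#'
#' Emulates a steady-state bench test of one restrictor: for each set-point
#' flow and replicate, the observed flow is `true * (1 + e_f)` and the
#' observed pressure drop is `law(true flow) * (1 + e_p)`, with independent
#' Gaussian relative errors at the instrument accuracies. The default sweep
#' covers 20 evenly spaced flows over 1-60 L/min (the validity range of the
#' quadratic laws) with 10 replicates each: 200 records per restrictor,
#' matching a standard bench campaign.
#'
#' @param law A [restrictor_law()] giving the true pressure-flow relation.
#' @param flows Set-point flows (L/min), all > 0.
#' @param n_reps Replicates per set point, >= 1.
#' @param noise A [bench_noise()] model (carries the seed).
#' @return A measurement set: a tibble with columns `flow_set_Lmin` (true
#'   set point), `flow_Lmin` (observed), `dp_cmH2O` (observed) and
#'   `replicate`, with the law's diameter in attribute `diameter`.
#' @examples
#' ms <- gen_bench_measurements(reference_law(2), noise = bench_noise(seed = 7))
#' nrow(ms) # 200
#' @export
gen_bench_measurements <- function(law,
                                   flows = seq(1, 60, length.out = 20),
                                   n_reps = 10,
                                   noise = bench_noise()) {
  stopifnot(inherits(law, "restrictor_law"), inherits(noise, "bench_noise"))
  if (any(flows <= 0)) stop_config("flows", "must be positive")
  if (n_reps < 1) stop_config("n_reps", "must be >= 1")
  grid <- tidyr::expand_grid(flow_set_Lmin = flows,
                             replicate = seq_len(n_reps))
  n <- nrow(grid)
  obs <- withr::with_seed(noise$seed, {
    e_f <- stats::rnorm(n, 0, noise$flow_relative_sd)
    e_p <- stats::rnorm(n, 0, noise$pressure_relative_sd)
    list(
      flow = grid$flow_set_Lmin * (1 + e_f),
      dp = quadratic_pressure_drop(law, grid$flow_set_Lmin) * (1 + e_p)
    )
  })
  out <- dplyr::mutate(grid, flow_Lmin = obs$flow, dp_cmH2O = obs$dp)
  attr(out, "diameter") <- law$diameter
  out
}

#' Generate a synthetic printed-wall radius profile
#'
#' Emulates the internal bore of a 3D-printed restrictor: a systematically
#' undersized mean radius, a layer-periodic sinusoidal ridge, and optional
#' Gaussian sampling noise:
#' `r(z) = (nominal - mean_undersize)/2 + (ridge_amplitude/2) sin(2 pi z / layer) + N(0, noise_sd)`.
#' The axial grid has `samples_per_layer` points per layer period (>= 8).
#'
#' @param nominal Design bore diameter (mm), > 0.
#' @param mean_undersize Mean diameter deficit (mm); must leave a positive
#'   bore.
#' @param ridge_amplitude Ridge feature size on the diameter scale (mm); the
#'   radius sinusoid has amplitude `ridge_amplitude / 2`, so
#'   [feature_size_fourier()] recovers this value directly.
#' @param layer_thickness Layer thickness = ridge period (mm), > 0.
#' @param length Axial span (mm); default 2.5 mm, a typical throat length
#'   giving >= 4 layer periods for all common layer heights.
#' @param noise_sd SD of additive radius noise (mm), >= 0.
#' @param samples_per_layer Grid density; >= 8.
#' @param seed Integer RNG seed.
#' @return A [wall_profile()].
#' @examples
#' p <- gen_wall_profile(2, 0.31, 0.10, 0.05, seed = 3)
#' summarize_profile(p)$mean_internal_diameter_mm # about 1.69
#' @export
gen_wall_profile <- function(nominal, mean_undersize, ridge_amplitude,
                             layer_thickness, length = 2.5, noise_sd = 0,
                             samples_per_layer = 16, seed = 1L) {
  check_number(nominal, "nominal", 0, strict_lower = TRUE)
  check_number(layer_thickness, "layer_thickness", 0, strict_lower = TRUE)
  check_number(noise_sd, "noise_sd", 0)
  if (samples_per_layer < 8) {
    stop_config("samples_per_layer", "need >= 8 samples per layer period")
  }
  if (nominal - mean_undersize <= 0) {
    stop_domain("mean_undersize leaves a non-physical bore")
  }
  dz <- layer_thickness / samples_per_layer
  z <- seq(0, length, by = dz)
  r0 <- (nominal - mean_undersize) / 2
  r <- r0 + (ridge_amplitude / 2) * sin(2 * pi * z / layer_thickness)
  if (noise_sd > 0) {
    r <- r + withr::with_seed(seed, stats::rnorm(length(z), 0, noise_sd))
  }
  if (any(r <= 0)) stop_domain("generated radii are non-physical")
  wall_profile(z, r, layer_thickness, nominal)
}
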