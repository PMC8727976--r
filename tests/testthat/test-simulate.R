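test_that("identity-restrictor branch matches the closed-form RC oracle", {
  w <- step_waveform(pip = 30, peep = 5, dt = 0.001)
  br <- branch_config("unrestricted", patient_params(0.2))
  res <- simulate_branch(w, br, opts = solver_opts(dt = 0.001))
  oracle <- step_response_volume(25, res$time_s, patient_params(0.2))
  expect_lt(max(abs(res$volume_L - oracle)), 1e-6)
  expect_equal(attr(res, "end_inspiratory_volume"),
               5 * (1 - exp(-1.25 / 7.088)), tolerance = 1e-6)
})

test_that("waveform at PEEP produces no flow and no volume", {
  w <- build_waveform(
    ventilator_settings(peak_pressure = 5 + 1e-9, peep = 5, rise_time = 0),
    dt = 0.005
  )
  # force the driving pressure to identically PEEP
  w$pressure_cmH2O[] <- 5
  br <- branch_config("idle", patient_params(0.1),
                      restrictor = reference_law(2))
  res <- simulate_branch(w, br, opts = fast_opts())
  expect_equal(max(abs(res$flow_Lmin)), 0, tolerance = 1e-9)
  expect_equal(max(abs(res$volume_L)), 0, tolerance = 1e-9)
})

test_that("a restrictor strictly reduces the delivered volume", {
  w <- step_waveform(dt = 0.005)
  free <- simulate_branch(w, branch_config("free", patient_params(0.1)),
                          opts = fast_opts())
  tight <- simulate_branch(
    w, branch_config("tight", patient_params(0.1),
                     restrictor = reference_law(2)),
    opts = fast_opts()
  )
  expect_lt(attr(tight, "end_inspiratory_volume"),
            attr(free, "end_inspiratory_volume"))
})

test_that("volumes are the trapezoidal integral of flows and non-decreasing", {
  w <- step_waveform(dt = 0.005)
  res <- simulate_branch(
    w, branch_config("r", patient_params(0.1), restrictor = reference_law(3)),
    opts = fast_opts()
  )
  dt <- diff(res$time_s)
  v_trap <- cumsum(c(0, dt * (head(res$flow_Lmin, -1) +
                                tail(res$flow_Lmin, -1)) / 2 / 60))
  expect_equal(res$volume_L, v_trap, tolerance = 1e-12)
  expect_true(all(diff(res$volume_L) >= 0))
  # summaries match the series
  expect_equal(attr(res, "peak_flow"), max(res$flow_Lmin))
  expect_equal(attr(res, "peak_pressure_drop"),
               max(res$restrictor_drop_cmH2O))
  expect_equal(attr(res, "end_inspiratory_volume"),
               res$volume_L[nrow(res)])
})

test_that("the restrictor only dissipates: drop * flow >= 0 throughout", {
  w <- build_waveform(ventilator_settings(rise_time = 0.2), dt = 0.005)
  res <- simulate_branch(
    w, branch_config("r", patient_params(0.1), restrictor = reference_law(2)),
    opts = fast_opts()
  )
  expect_true(all(res$restrictor_drop_cmH2O * res$flow_Lmin >= 0))
})

test_that("halving dt changes the end-inspiratory volume by < 0.1%", {
  w <- step_waveform(dt = 0.001)
  br <- branch_config("r", patient_params(0.1),
                      restrictor = reference_law(2))
  v1 <- attr(simulate_branch(w, br, opts = solver_opts(dt = 0.001)),
             "end_inspiratory_volume")
  v2 <- attr(simulate_branch(w, br, opts = solver_opts(dt = 0.0005)),
             "end_inspiratory_volume")
  expect_lt(abs(v1 - v2) / v2, 0.001)
})

test_that("splitter branches decouple: summary invariant to the other side", {
  w <- step_waveform(dt = 0.005)
  unres <- branch_config("unrestricted", patient_params(0.2))
  sweep <- lapply(c(2, 3, 4), function(d) {
    res <- simulate_splitter(
      w, list(branch_config("restricted", patient_params(0.1),
                            restrictor = reference_law(d)),
              unres),
      opts = fast_opts()
    )
    dplyr::filter(res$summary, branch == "unrestricted")
  })
  expect_equal(sweep[[1]], sweep[[2]])
  expect_equal(sweep[[1]], sweep[[3]])
})

test_that("two identical unrestricted branches behave identically", {
  w <- step_waveform(dt = 0.005)
  res <- simulate_splitter(
    w, list(branch_config("a", patient_params(0.1)),
            branch_config("b", patient_params(0.1))),
    opts = fast_opts()
  )
  expect_equal(res$branches$a$volume_L, res$branches$b$volume_L)
  expect_equal(res$summary$end_inspiratory_volume_L[1],
               res$summary$end_inspiratory_volume_L[2])
})

test_that("restricted-branch end volume increases with bore diameter", {
  w <- step_waveform(dt = 0.005)
  vols <- vapply(list(reference_law(2), reference_law(3), reference_law(4),
                      identity_law()), function(law) {
    res <- simulate_branch(
      w, branch_config("r", patient_params(0.1), restrictor = law),
      opts = fast_opts()
    )
    attr(res, "end_inspiratory_volume")
  }, numeric(1))
  expect_true(all(diff(vols) > 0))
})

test_that("an optional common series resistance couples the branches", {
  w <- step_waveform(dt = 0.01)
  branches <- list(
    branch_config("restricted", patient_params(0.1),
                  restrictor = reference_law(4)),
    branch_config("unrestricted", patient_params(0.2))
  )
  free <- simulate_splitter(w, branches, opts = fast_opts(0.01))
  shared <- simulate_splitter(w, branches, opts = fast_opts(0.01),
                              common_law = restrictor_law(a = 0.01, b = 0.1))
  # a shared upstream loss must reduce both delivered volumes
  expect_true(all(shared$summary$end_inspiratory_volume_L <
                    free$summary$end_inspiratory_volume_L))
  # and an identity common law must change nothing
  same <- simulate_splitter(w, branches, opts = fast_opts(0.01),
                            common_law = identity_law())
  expect_equal(same$summary, free$summary)
})

test_that("branch and splitter validation errors are informative", {
  w <- step_waveform(dt = 0.01)
  expect_error(branch_config("", patient_params(0.1)),
               class = "ventsplitr_config_error")
  expect_error(
    simulate_splitter(w, list(branch_config("x", patient_params(0.1)))),
    class = "ventsplitr_config_error"
  )
  expect_error(
    simulate_splitter(w, list(branch_config("x", patient_params(0.1)),
                              branch_config("x", patient_params(0.2)))),
    class = "ventsplitr_config_error"
  )
})
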