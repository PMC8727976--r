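test_that("noiseless data are recovered exactly with R^2 = 1", {
  law <- restrictor_law(diameter = 2, a = 0.22444, b = 0.88262)
  ms <- gen_bench_measurements(law, flows = c(5, 10, 20, 40, 60), n_reps = 2,
                               noise = bench_noise(0, 0, seed = 1))
  fit <- fit_quadratic_law(ms)
  expect_equal(fit$a, 0.22444, tolerance = 1e-9)
  expect_equal(fit$b, 0.88262, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1)
  expect_equal(glance(fit)$diameter_mm, 2)
})

test_that("fits recover truth under instrument noise with high R^2", {
  law <- restrictor_law(diameter = 2, a = 0.22444, b = 0.88262)
  ms <- gen_bench_measurements(law, noise = bench_noise(seed = 11))
  fit <- fit_quadratic_law(ms)
  expect_lt(abs(fit$a - law$a), 3 * fit$std_error_a)
  expect_lt(abs(fit$b - law$b), 3 * fit$std_error_b)
  expect_gte(fit$r_squared, 0.99)
  td <- tidy(fit)
  expect_equal(td$term, c("a", "b"))
  expect_equal(td$estimate, c(fit$a, fit$b))
})

test_that("a purely linear law yields a fitted quadratic term within noise", {
  law <- restrictor_law(a = 0, b = 0.5)
  ms <- gen_bench_measurements(law, noise = bench_noise(seed = 3))
  fit <- fit_quadratic_law(ms)
  expect_lt(abs(fit$a), 3 * fit$std_error_a)
  constrained <- fit_quadratic_law(ms, constrain_nonnegative = TRUE)
  expect_gte(constrained$a, 0)
  expect_gte(constrained$b, 0)
})

test_that("fitting is scale-equivariant and rejects degenerate designs", {
  law <- restrictor_law(diameter = 3, a = 0.04, b = 0.26)
  ms <- gen_bench_measurements(law, noise = bench_noise(seed = 5))
  f1 <- fit_quadratic_law(ms)
  ms2 <- dplyr::mutate(ms, dp_cmH2O = 3.5 * dp_cmH2O)
  f2 <- fit_quadratic_law(ms2)
  expect_equal(f2$a, 3.5 * f1$a, tolerance = 1e-10)
  expect_equal(f2$b, 3.5 * f1$b, tolerance = 1e-10)
  flat <- tibble::tibble(flow_Lmin = rep(10, 5), dp_cmH2O = rep(3, 5))
  expect_error(fit_quadratic_law(flat), class = "ventsplitr_fit_error")
})

test_that("bootstrap standard errors agree with OLS to the right order", {
  law <- restrictor_law(diameter = 2, a = 0.22444, b = 0.88262)
  ms <- gen_bench_measurements(law, noise = bench_noise(seed = 2))
  fit <- fit_quadratic_law(ms, n_boot = 200, boot_seed = 7)
  expect_gt(fit$boot_se_a, fit$std_error_a / 2)
  expect_lt(fit$boot_se_a, fit$std_error_a * 2)
  expect_gt(fit$boot_se_b, fit$std_error_b / 2)
  expect_lt(fit$boot_se_b, fit$std_error_b * 2)
  expect_equal(names(tidy(fit)),
               c("term", "estimate", "std.error", "boot.std.error"))
})

test_that("log-log meta-fit recovers exact power laws and interpolates pairs", {
  truth <- powerlaw_model(k_a = 2.5, m_a = -3.7, k_b = 8, m_b = -2.9)
  d <- c(2, 2.5, 3, 3.5, 4)
  tab <- tibble::tibble(diameter = d,
                        a = truth$k_a * d^truth$m_a,
                        b = truth$k_b * d^truth$m_b)
  fit <- fit_power_laws(tab)
  expect_equal(fit$k_a, truth$k_a, tolerance = 1e-10)
  expect_equal(fit$m_a, truth$m_a, tolerance = 1e-10)
  expect_equal(fit$k_b, truth$k_b, tolerance = 1e-10)
  expect_equal(fit$m_b, truth$m_b, tolerance = 1e-10)
  # two points: exact interpolation through the log pair
  two <- tab[c(1, 5), ]
  fit2 <- fit_power_laws(two)
  expect_equal(fit2$m_a, log(two$a[2] / two$a[1]) / log(2), tolerance = 1e-10)
  expect_error(fit_power_laws(tibble::tibble(diameter = 2, a = 1, b = 1)),
               class = "ventsplitr_domain_error")
  expect_error(
    fit_power_laws(tibble::tibble(diameter = c(2, 3), a = c(1, -1),
                                  b = c(1, 1))),
    class = "ventsplitr_domain_error"
  )
})

test_that("power-law fit round-trips with powerlaw_pressure_drop", {
  truth <- reference_powerlaw_model()
  d <- seq(2, 4, by = 0.5)
  tab <- tibble::tibble(
    diameter = d,
    a = truth$k_a * d^truth$m_a,
    b = truth$k_b * d^truth$m_b
  )
  refit <- fit_power_laws(tab)
  v <- c(5, 20, 45)
  for (dd in d) {
    expect_equal(powerlaw_pressure_drop(dd, v, refit),
                 powerlaw_pressure_drop(dd, v, truth), tolerance = 1e-10)
  }
})

test_that("effective diameter inverts the power law", {
  expect_equal(effective_diameter_from_fit(list(a = 3.55)), 1)
  expect_equal(effective_diameter_from_fit(list(a = 0.22444)), 2,
               tolerance = 0.01)
  # end-to-end: bench data from a synthetic undersized part (true bore 1.69)
  law <- law_at_diameter(1.69)
  ms <- gen_bench_measurements(law, noise = bench_noise(seed = 21))
  est <- effective_diameter_from_fit(fit_quadratic_law(ms))
  expect_equal(est, 1.69, tolerance = 0.03)
  expect_error(effective_diameter_from_fit(list(a = -1)),
               class = "ventsplitr_domain_error")
})
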