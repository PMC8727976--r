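gas <- gas_properties()

test_that("Reynolds number matches hand arithmetic and its scaling laws", {
  expect_equal(reynolds_number(0, 2), 0)
  # 4 * 1.1e-4 / (pi * 0.002 * 2.02e-5)
  expect_equal(reynolds_number(6.6, 2, gas),
               4 * (6.6 / 60000) / (pi * 0.002 * 2.02e-5))
  expect_equal(reynolds_number(6.6, 2, gas), 3467, tolerance = 1e-3)
  # the true-bore operating point of an undersized 2 mm part sits at the
  # lower edge of the 5000-8000 turbulent band
  re <- reynolds_number(8.04, 1.69, gas)
  expect_equal(re, 5000, tolerance = 0.01)
  # linear in flow, inverse in diameter
  expect_equal(reynolds_number(20, 3, gas), 2 * reynolds_number(10, 3, gas))
  expect_equal(reynolds_number(10, 2, gas), 2 * reynolds_number(10, 4, gas))
  expect_error(reynolds_number(5, 0), class = "ventsplitr_domain_error")
})

test_that("orifice pressure drop matches SI arithmetic and D^-4 scaling", {
  # independent SI route: dynamic pressure through the vena contracta
  rho <- 101325 / (265 * 293)
  q <- 6.6 / 60000
  dp_pa <- 8 * rho * q^2 / (pi^2 * 0.8^2 * 0.002^4)
  expect_equal(orifice_pressure_drop(6.6, 2, 0.8, gas), dp_pa / 98.0665)
  expect_equal(orifice_pressure_drop(6.6, 2, 0.8, gas), 12.74,
               tolerance = 1e-3)
  expect_equal(orifice_pressure_drop(0, 2, 0.8, gas), 0)
  # halving the bore multiplies the drop by exactly 16
  expect_equal(orifice_pressure_drop(6.6, 1, 0.8, gas),
               16 * orifice_pressure_drop(6.6, 2, 0.8, gas))
  # antisymmetric in flow
  expect_equal(orifice_pressure_drop(-6.6, 2, 0.8, gas),
               -orifice_pressure_drop(6.6, 2, 0.8, gas))
  expect_error(orifice_pressure_drop(5, 2, 1.2, gas),
               class = "ventsplitr_domain_error")
})

test_that("quadratic law reproduces the reference peak pressure drops", {
  laws <- ref_laws()
  # 4 mm law at the printed peak flow reproduces the printed peak drop
  expect_equal(quadratic_pressure_drop(laws[["4"]], 20.4), 7.40,
               tolerance = 0.01 / 7.40)
  # 3 mm: peak drop and peak flow are not exactly simultaneous upstream,
  # so agreement is to ~2%
  expect_equal(quadratic_pressure_drop(laws[["3"]], 14.0), 11.21,
               tolerance = 0.02)
  expect_equal(quadratic_pressure_drop(laws[["2"]], 6.6), 15.22,
               tolerance = 0.03)
  expect_equal(quadratic_pressure_drop(laws[["2"]], 0), 0)
})

test_that("quadratic law is odd and strictly increasing in flow", {
  laws <- ref_laws()
  flows <- seq(0.5, 60, length.out = 40)
  for (law in laws) {
    dp <- quadratic_pressure_drop(law, flows)
    expect_equal(quadratic_pressure_drop(law, -flows), -dp)
    if (law$a + law$b > 0) expect_true(all(diff(dp) > 0))
  }
})

test_that("power-law model evaluates correctly and tracks the quadratic laws", {
  expect_equal(powerlaw_pressure_drop(3, 14), 11.53, tolerance = 1e-3)
  expect_equal(powerlaw_pressure_drop(3, 14), 11.21, tolerance = 0.03)
  expect_equal(powerlaw_pressure_drop(2, 6.6), 15.22, tolerance = 0.03)
  expect_equal(powerlaw_pressure_drop(2.5, 0), 0)
  expect_warning(powerlaw_pressure_drop(1.5, 10), "validity range")
  expect_error(powerlaw_pressure_drop(-1, 10),
               class = "ventsplitr_domain_error")
  # monotone decreasing in diameter at fixed flow
  dd <- seq(2, 4, by = 0.25)
  expect_true(all(diff(powerlaw_pressure_drop(dd, 20)) < 0))
  # meta-fit residual: within 7% of the per-diameter laws once the
  # quadratic term matters (V >= 3 L/min); the linear-coefficient residual
  # alone reaches ~12% as V -> 0
  laws <- ref_laws()
  for (d in c(2, 3, 4)) {
    v <- seq(3, 60, length.out = 30)
    rel <- abs(powerlaw_pressure_drop(d, v) /
                 quadratic_pressure_drop(laws[[as.character(d)]], v) - 1)
    expect_lt(max(rel), 0.07)
  }
})

test_that("diameter sensitivity is the fourth-power ratio", {
  expect_equal(diameter_sensitivity(2, 2), 1)
  expect_equal(diameter_sensitivity(2, 1), 16)
  expect_equal(diameter_sensitivity(2.00, 1.69), (2 / 1.69)^4)
  expect_equal(diameter_sensitivity(2.00, 1.69), 1.96, tolerance = 0.005)
  expect_equal(diameter_sensitivity(2.00, 1.38), 4.41, tolerance = 0.005)
  expect_error(diameter_sensitivity(0, 1), class = "ventsplitr_domain_error")
})

test_that("mean resistance is the secant resistance in cmH2O/(L/s)", {
  laws <- ref_laws()
  expect_equal(mean_resistance(laws[["none"]], 10), 0.2166)
  expect_equal(round(mean_resistance(laws[["none"]], 30), 2), 0.22)
  expect_equal(mean_resistance(restrictor_law(a = 0, b = 1), 10), 60)
  # an operating flow of ~7.65 L/min puts the 2 mm part near its quoted
  # mean resistance of 156
  expect_equal(mean_resistance(laws[["2"]], 7.65), 156, tolerance = 0.005)
})

test_that("restrictor laws serialize to JSON with unit-tagged keys", {
  law <- restrictor_law(diameter = 3, a = 0.03961, b = 0.26081)
  f <- withr::local_tempfile(fileext = ".json")
  write_law_json(law, f)
  txt <- paste(readLines(f), collapse = "")
  expect_match(txt, "a_cmH2O_per_Lmin2")
  back <- read_law_json(f)
  expect_equal(back$a, law$a)
  expect_equal(back$b, law$b)
  expect_equal(back$diameter, 3)
})
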