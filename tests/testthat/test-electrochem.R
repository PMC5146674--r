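test_that("charge integration is exact for constant and linear traces", {
  expect_equal(integrate_charge(current_trace(c(0, 1000),
                                              c(0.001, 0.001))), 1.0)
  # triangle area of a linear ramp
  expect_equal(integrate_charge(current_trace(c(0, 1000),
                                              c(0, 0.002))), 1.0)
  expect_error(integrate_charge(data.frame(time_s = 0, current_A = 1)),
               "2 samples")
})

test_that("charge integration matches a fine Riemann oracle on random traces", {
  set.seed(11)
  for (i in 1:5) {
    tr <- current_trace(sort(runif(200, 0, 36000)),
                        runif(200, 0, 5e-3))
    expect_equal(integrate_charge(tr), riemann_charge(tr),
                 tolerance = 1e-9)
  }
})

test_that("coulombic efficiency reproduces its definition", {
  # identity: all donor electrons as charge
  expect_equal(coulombic_efficiency(96485 * 14 * 0.00144, 0.00144, 14),
               100)
  expect_equal(coulombic_efficiency(1381.1, 1.44e-3, 14), 71.0,
               tolerance = 1e-3)
  expect_equal(coulombic_efficiency(0, 1e-3, 14), 0)
  expect_error(coulombic_efficiency(10, 0, 14), "> 0")
  expect_warning(coulombic_efficiency(2 * 96485 * 14 * 1e-3, 1e-3, 14),
                 "exceeds 100")
})

test_that("CE is linear in charge and inversely proportional to donor", {
  set.seed(3)
  for (i in 1:10) {
    q <- runif(1, 10, 2000); n <- runif(1, 1e-4, 5e-3)
    k <- runif(1, 0.5, 3)
    base <- suppressWarnings(coulombic_efficiency(q, n, 14))
    expect_equal(suppressWarnings(coulombic_efficiency(k * q, n, 14)),
                 k * base)
    expect_equal(suppressWarnings(coulombic_efficiency(q, k * n, 14)),
                 base / k)
  }
})

test_that("volumetric current density and H2 rate reproduce the printed scale", {
  expect_equal(volumetric_current_density(4.12e-3, 4e-5), 103)
  expect_equal(volumetric_current_density(0, 4e-5), 0)
  expect_equal(volumetric_current_density(3.08e-3, 4e-5), 77)
  expect_error(volumetric_current_density(1e-3, 0), "> 0")
  expect_equal(h2_production_rate(8.8e-5, 4, 4e-5), 0.55)
  expect_equal(h2_production_rate(0, 4, 4e-5), 0)
  expect_equal(h2_production_rate(4.48e-5, 4, 4e-5), 0.28)
  expect_error(h2_production_rate(1e-5, 0, 4e-5), "> 0")
})

test_that("H2 yield and its stoichiometric ceiling", {
  expect_equal(h2_yield(8.496e-3, 1.44e-3), 5.9)
  expect_equal(h2_yield(0, 1e-3), 0)
  expect_error(h2_yield(1e-3, 0), "> 0")
  expect_equal(h2_yield_ceiling("propionate"), 7)
  expect_equal(h2_yield_ceiling("acetate"), 4)
})

test_that("substrate removal extent and rate", {
  r <- substrate_removal(36, 0, 3.0)
  expect_equal(r$removal_pct, 100)
  expect_equal(r$rate_mM_day, 12)
  expect_equal(substrate_removal(36, 0, 3.43)$rate_mM_day, 10.5,
               tolerance = 1e-3)
  r0 <- substrate_removal(36, 36, 2)
  expect_equal(r0$removal_pct, 0)
  expect_equal(r0$rate_mM_day, 0)
  expect_warning(rn <- substrate_removal(30, 36, 2), "negative removal")
  expect_lt(rn$removal_pct, 0)
})

test_that("ideal-gas conversion reproduces molar volumes", {
  expect_equal(gas_moles(24.87, 303.15, 1), 1e-3, tolerance = 1e-3)
  expect_equal(gas_moles(0), 0)
  expect_equal(gas_moles(22.41, 273.15, 1), 1e-3, tolerance = 1e-3)
  # inverse round trip
  expect_equal(gas_volume_m3(gas_moles(50, 298, 1), 298, 1) * 1e6, 50)
})

test_that("trace validation rejects malformed telemetry", {
  expect_error(current_trace(c(0, 0), c(1, 1)), "strictly increasing")
  expect_error(current_trace(0, 1), "2 samples")
  expect_error(current_trace(c(0, 1), c(-1, -2)), "negative mean")
  # slightly negative samples are tolerated
  expect_s3_class(current_trace(c(0, 1, 2), c(-1e-5, 2e-3, 1e-3)),
                  "current_trace")
})

test_that("peak current uses a moving-median smooth", {
  tr <- current_trace(seq(0, 5000, 600),
                      c(1e-3, 1e-3, 50e-3, 1e-3, 1e-3, 1e-3, 1e-3,
                        1e-3, 1e-3))
  expect_equal(peak_current(tr), 1e-3)        # spike suppressed
  expect_equal(peak_current(tr, window = 1), 50e-3)
})
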