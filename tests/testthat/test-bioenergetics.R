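test_that("anode energy gain reproduces the standard-condition grid", {
  grid <- list(acetate = c(`-0.25` = -21.6, `0` = -214.6, `0.25` = -407.6),
               H2      = c(`-0.25` = -31.5, `0` = -79.7,  `0.25` = -127.9),
               formate = c(`-0.25` = -46.1, `0` = -94.4,  `0.25` = -142.6))
  for (donor in names(grid)) {
    got <- anode_energy_gain(c(-0.25, 0, 0.25), donor, profile = "paper")
    expect_equal(got, unname(grid[[donor]]), info = donor)
  }
})

test_that("zero overpotential yields zero energy gain", {
  dc <- donor_couples("paper")
  for (i in seq_len(nrow(dc))) {
    expect_equal(anode_energy_gain(dc$E0prime_V[i], dc$donor[i]), 0)
  }
})

test_that("energy gain is affine in the anode potential with slope -nF", {
  dc <- donor_couples("paper")
  for (i in seq_len(nrow(dc))) {
    cp <- redox_couple(dc$donor[i], dc$n[i], dc$E0prime_V[i])
    g <- anode_energy_gain(c(-0.1, 0.1, 0.3), cp)
    slope1 <- (g[2] - g[1]) / 0.2
    slope2 <- (g[3] - g[2]) / 0.2
    expect_equal(slope1, -dc$n[i] * 96485 / 1000, tolerance = 1e-2)
    expect_equal(slope2, slope1, tolerance = 1e-2)
    # printed-grid consistency: dG(0.25) - dG(0) = -n F 0.25
    expect_equal(anode_energy_gain(0.25, cp) - anode_energy_gain(0, cp),
                 -dc$n[i] * 96485 * 0.25 / 1000, tolerance = 0.11)
  }
})

test_that("both constants profiles are available and differ as documented", {
  lit <- donor_couples("literature")
  expect_equal(lit$E0prime_V[lit$donor == "formate"], -0.432)
  expect_equal(anode_energy_gain(0, "acetate", profile = "literature"),
               round(-8 * 96485 * 0.290 / 1000, 1))
})

test_that("reaction free energies reproduce the methanogenesis values", {
  expect_equal(reaction_deltaG(c(H2 = -4, HCO3 = -1, `H+` = -1, CH4 = 1,
                                 H2O = 3)), -135.6)
  expect_equal(reaction_deltaG(c(acetate = -1, H2O = -1, CH4 = 1,
                                 HCO3 = 1)), -31.0)
  expect_equal(reaction_deltaG(c(formate = -4, H2O = -1, `H+` = -1,
                                 CH4 = 1, HCO3 = 3)), -130.1)
  expect_equal(reaction_deltaG(numeric(0)), 0)
})

test_that("reaction validation catches imbalance and missing data", {
  expect_error(reaction_deltaG(c(H2 = -3, HCO3 = -1, `H+` = -1, CH4 = 1,
                                 H2O = 3)), "not balanced")
  reg <- compound_registry()
  reg$CH4$dGf <- NA_real_
  expect_error(reaction_deltaG(c(acetate = -1, H2O = -1, CH4 = 1,
                                 HCO3 = 1), registry = reg),
               "missing dGf.*CH4")
})

test_that("free energies are additive over summed reactions (Hess)", {
  rx <- methanogenic_reactions()
  combine <- function(s1, s2) {
    nm <- union(names(s1), names(s2))
    out <- setNames(numeric(length(nm)), nm)
    out[names(s1)] <- s1
    out[names(s2)] <- out[names(s2)] + s2
    out[out != 0]
  }
  set.seed(9)
  for (i in 1:5) {
    pair <- sample(rx, 2)
    s <- combine(pair[[1]]$stoichiometry, pair[[2]]$stoichiometry)
    expect_equal(reaction_deltaG(s),
                 reaction_deltaG(pair[[1]]$stoichiometry) +
                   reaction_deltaG(pair[[2]]$stoichiometry),
                 tolerance = 0.2)  # one-decimal rounding of each term
  }
})

test_that("favorability ranking flips from methane to current with potential", {
  fm <- favorability_matrix(c(-0.25, 0, 0.25), "acetate")
  expect_equal(fm$preferred[fm$e_anode_V == -0.25], "methane")
  expect_equal(fm$preferred[fm$e_anode_V == 0], "current")
  expect_equal(fm$dG_current_kJ_mol, c(-21.6, -214.6, -407.6))
  expect_equal(unique(fm$dG_ch4_kJ_rxn), -31.0)
  # zero overpotential vs an exergonic methanogenic route
  fm0 <- favorability_matrix(-0.278, "acetate")
  expect_equal(fm0$preferred, "methane")
  # H2 route compared per mol donor
  fmh <- favorability_matrix(-0.25, "H2")
  expect_equal(fmh$dG_ch4_kJ_mol, -135.6 / 4)
  expect_equal(fmh$preferred, "methane")
})
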