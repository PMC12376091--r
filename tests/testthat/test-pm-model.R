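test_that("closest-approach table follows the additivity rule", {
  m <- rpm22()
  expect_equal(m$closest_approach["M", "X"], 4.6)
  m2 <- pm_model(list(pm_species("M", 2, 2.0), pm_species("X", -2, 4.6)))
  expect_equal(m2$closest_approach["M", "X"], 3.3)
  expect_equal(m2$closest_approach["M", "M"], 2.0)
  # degenerate single neutral species still builds a valid model
  m3 <- pm_model(list(pm_species("A", 0, 1.0)), epsilon_r = 10)
  expect_equal(dim(m3$closest_approach), c(1L, 1L))
})

test_that("construction rejects invalid fields by name", {
  expect_error(pm_species("A", 1, -1), "diameter")
  expect_error(pm_species("A", 1, 2, polarizability_volume = -1),
               "polarizability")
  expect_error(pm_model(list(pm_species("A", 0, 1)), epsilon_r = 1),
               "epsilon_r")
  expect_error(pm_model(list(pm_species("A", 0, 1)), temperature = -5),
               "temperature")
  expect_error(pm_model(list(pm_species("A", 0, 1), pm_species("A", 1, 1))),
               "unique")
})

test_that("Bjerrum length matches CODATA constants and scaling laws", {
  # e^2/(4 pi eps0 eps_r kB T) for water at 25 C
  expect_equal(bjerrum_length(78.36, 298.15), 7.152365, tolerance = 1e-6)
  m <- rpm22()
  expect_equal(bjerrum_length(m), bjerrum_length(78.36, 298.15))
  # halves exactly when eps_r doubles; proportional to 1/eps_r
  expect_equal(bjerrum_length(2 * 78.36, 298.15),
               bjerrum_length(78.36, 298.15) / 2)
  expect_equal(bjerrum_length(1, 298.15),
               78.36 * bjerrum_length(78.36, 298.15))
})

test_that("pair potential: hard core, Coulomb tail, symmetry", {
  m <- rpm22()
  neutral <- pm_model(list(pm_species("A", 0, 2), pm_species("B", 0, 3)))
  expect_identical(pair_potential(neutral, "A", "B", 10), 0)
  expect_identical(pair_potential(m, "M", "X", 0.99 * 4.6), Inf)
  # two +2 charges at r = l_B interact with 4 kT
  lB <- bjerrum_length(m)
  expect_equal(pair_potential(m, "M", "M", lB), 4.0, tolerance = 1e-12)
  # symmetry and decay to zero
  r <- seq(4.6, 60, by = 0.7)
  expect_equal(pair_potential(m, "M", "X", r), pair_potential(m, "X", "M", r))
  expect_lt(abs(pair_potential(m, "M", "X", 1e5)), 1e-3)
  expect_error(pair_potential(m, "M", "Z", 5), "unknown species")
  expect_error(pair_potential(m, "M", "X", -1), "positive")
})

test_that("charge scaling multiplies the potential by factor^2", {
  m <- rpm22()
  expect_equal(unname(scale_charges(m, 0.5)$charge), c(1, -1))
  expect_equal(unname(scale_charges(m, 0.75)$charge), c(1.5, -1.5))
  expect_equal(scale_charges(m, 1)$charge, m$charge)
  expect_error(scale_charges(m, 0), "factor")
  s <- 0.37
  r <- seq(4.6, 30, by = 1.1)
  expect_equal(pair_potential(scale_charges(m, s), "M", "X", r),
               s^2 * pair_potential(m, "M", "X", r))
})

test_that("molality-density conversion and its inverse round-trip", {
  m <- rpm11()
  st0 <- molality_to_state(m, 0, c(M = 1, X = 1))
  expect_true(all(st0$number_densities == 0))
  st1 <- molality_to_state(m, 1.0, c(M = 1, X = 1))
  # 1 mol/kg * N_A * 997 kg/m^3 * 1e-30 = 6.004e-4 per cubic angstrom
  expect_equal(unname(st1$number_densities["M"]), 6.004074e-4,
               tolerance = 1e-6)
  expect_equal(state_to_molality(st1, c(M = 1, X = 1)), 1.0,
               tolerance = 1e-12)
  expect_error(molality_to_state(m, 1, c(M = 1)), "electroneutral")
  expect_error(pm_state(m, c(M = 1e-4, X = 2e-4)), "electroneutral")
})

test_that("box composition helpers reproduce known solution arithmetic", {
  # 12 ion pairs per 665 waters is very nearly a 1 molal solution
  expect_equal(composition_molality(12, 665), 12 / (665 * 0.018015))
  expect_equal(composition_molality(12, 665), 1.0, tolerance = 0.01)
  edge <- solution_box_edge(12, 665)
  expect_gt(edge, 25)
  expect_lt(edge, 30)
})

test_that("model definition files round-trip", {
  m <- pm_model(list(pm_species("Mg", 2, 2.4, polarizability_volume = 0),
                     pm_species("SO4", -2, 4.6, polarizability_volume = 5)),
                epsilon_r = 78.36, temperature = 298.15)
  path <- withr::local_tempfile(fileext = ".toml")
  write_pm_model(m, path)
  m2 <- read_pm_model(path)
  expect_equal(m2$charge, m$charge)
  expect_equal(m2$diameter, m$diameter)
  expect_equal(m2$closest_approach, m$closest_approach)
  expect_equal(m2$epsilon_r, m$epsilon_r)
  expect_equal(m2$species[[2]]$polarizability_volume, 5)
})

test_that("shipped model fixture encodes the PM defaults", {
  path <- system.file("extdata", "pm_mgso4.toml", package = "ionpair")
  m <- read_pm_model(path)
  expect_equal(m$epsilon_r, 78.36)
  expect_equal(m$temperature, 298.15)
  expect_equal(unname(m$diameter[m$charge < 0]), 4.6)
  expect_equal(unname(sort(m$charge)), c(-2, 2))
})
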