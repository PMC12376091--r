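test_that("zero-density limit reduces to the Boltzmann factor", {
  mod <- rpm11()
  st <- pm_state(mod, c(M = 1e-12, X = 1e-12))
  corr <- suppressWarnings(solve_hnc(mod, st, radial_grid(2^12, 0.02)))
  r <- corr$grid$r
  out <- r > 4.6 & r < 40
  g_expect <- exp(-pair_potential(mod, "M", "X", r[out]))
  expect_lt(max(abs(corr$g[out, "M", "X"] - g_expect)), 1e-3)
  g_expect_mm <- exp(-pair_potential(mod, "M", "M", r[out]))
  expect_lt(max(abs(corr$g[out, "M", "M"] - g_expect_mm)), 1e-3)
})

test_that("uncharged hard spheres match the Carnahan-Starling contact value", {
  eta <- 0.05
  hs <- pm_model(list(pm_species("A", 0, 1)))
  st <- pm_state(hs, c(A = 6 * eta / pi))
  corr <- suppressWarnings(solve_hnc(hs, st, radial_grid(2^13, 0.002)))
  g_contact <- ionpair:::.contact_value(corr$grid$r, corr$g[, 1, 1], 1)
  cs <- (1 - eta / 2) / (1 - eta)^3
  expect_equal(g_contact, cs, tolerance = 0.02)
})

test_that("pair-correlation invariants hold on a converged 2:2 solution", {
  corr <- corr22_m05()
  expect_true(corr$converged)
  # g = h + 1 everywhere
  expect_equal(corr$g, corr$h + 1, tolerance = 1e-12)
  # core exclusion and long-range limit
  core <- corr$grid$r < 4.6
  expect_lt(max(abs(corr$g[core, "M", "X"])), 1e-10)
  n <- corr$grid$n_points
  expect_lt(max(abs(corr$g[n - 5:0, , ] - 1)), 1e-3)
  # local electroneutrality: each ion carries -q_i of screening charge
  sc <- screening_charge(corr)
  expect_equal(unname(sc), c(-2, 2), tolerance = 0.02)
})

test_that("osmotic coefficient: ideal and second-virial limits", {
  mod <- rpm22()
  st0 <- pm_state(mod, c(M = 0, X = 0))
  corr0 <- solve_hnc(mod, st0, radial_grid(2^12, 0.02))
  expect_identical(osmotic_coefficient(corr0), 1)
  # dilute uncharged hard spheres: phi -> 1 + B2 rho
  hs <- pm_model(list(pm_species("A", 0, 1)))
  rho <- 0.01 * 6 / pi
  st <- pm_state(hs, c(A = rho))
  corr <- suppressWarnings(solve_hnc(hs, st, radial_grid(2^12, 0.005)))
  expect_equal(osmotic_coefficient(corr), 1 + 2 * pi / 3 * rho,
               tolerance = 0.01)
})

test_that("excess Coulomb energy: zero for neutral, negative for a salt", {
  hs <- pm_model(list(pm_species("A", 0, 1)))
  st <- pm_state(hs, c(A = 0.01))
  corr <- suppressWarnings(solve_hnc(hs, st, radial_grid(2^12, 0.005)))
  expect_identical(excess_coulomb_energy(corr), 0)
  expect_lt(excess_coulomb_energy(corr22_m05()), 0)
})

test_that("solution is invariant under species relabeling", {
  g <- radial_grid(2^12, 0.025)
  m1 <- rpm11()
  st1 <- molality_to_state(m1, 0.5, c(M = 1, X = 1))
  c1 <- suppressWarnings(solve_hnc(m1, st1, g))
  m2 <- pm_model(list(pm_species("X", -1, 4.6), pm_species("M", 1, 4.6)))
  st2 <- molality_to_state(m2, 0.5, c(M = 1, X = 1))
  c2 <- suppressWarnings(solve_hnc(m2, st2, g))
  expect_equal(c1$g[, "M", "X"], c2$g[, "M", "X"], tolerance = 1e-7)
  expect_equal(osmotic_coefficient(c1), osmotic_coefficient(c2),
               tolerance = 1e-6)
})

test_that("phi is continuous along a density-stepping path", {
  mod <- rpm22()
  grid <- radial_grid(2^13, 0.025)
  ms <- seq(0.1, 0.4, by = 0.05)
  prev <- NULL
  phis <- numeric(0)
  for (m in ms) {
    st <- molality_to_state(mod, m, c(M = 1, X = 1))
    prev <- suppressWarnings(solve_hnc(mod, st, grid, init = prev))
    phis <- c(phis, osmotic_coefficient(prev))
  }
  expect_true(all(abs(diff(phis)) < 0.05))
})

test_that("unconverged results are refused, never silently used", {
  corr <- corr22_m05()
  broken <- corr
  broken$converged <- FALSE
  expect_error(osmotic_coefficient(broken), "unconverged")
  expect_error(excess_coulomb_energy(broken), "unconverged")
  # the solver itself raises a typed condition on iteration exhaustion
  mod <- rpm22()
  st <- molality_to_state(mod, 0.5, c(M = 1, X = 1))
  expect_error(
    suppressWarnings(solve_hnc(mod, st, radial_grid(2^12, 0.025),
                               max_iter = 3L)),
    class = "hnc_nonconvergence")
})

test_that("radial grid validates its invariants", {
  expect_error(radial_grid(1000, 0.02), "power of two")
  expect_error(radial_grid(2^12, 0.1), "dr")
  g <- radial_grid(2^12, 0.02)
  expect_equal(g$r[1], 0.02)
  expect_equal(length(g$r), 2^12)
})
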