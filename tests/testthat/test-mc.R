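test_that("Ewald energy matches the direct Coulomb pair at short range", {
  mod <- rpm11()
  lB <- bjerrum_length(mod)
  cfg <- configuration(rbind(c(0, 0, 0), c(3, 0, 0)), c("M", "X"), 200)
  U <- ewald_energy(cfg, mod)
  expect_equal(U, -lB / 3, tolerance = 5e-3)
  # zero charges give exactly zero
  neutral <- pm_model(list(pm_species("M", 0, 1), pm_species("X", 0, 1)))
  expect_equal(ewald_energy(cfg, neutral), 0)
})

test_that("Ewald energy reproduces the NaCl Madelung constant", {
  mod <- rpm11()
  lB <- bjerrum_length(mod)
  L <- 10
  a <- L / 2
  g <- expand.grid(x = 0:1, y = 0:1, z = 0:1)
  cfg <- configuration(as.matrix(g) * a,
                       ifelse((-1)^(g$x + g$y + g$z) > 0, "M", "X"), L)
  U <- ewald_energy(cfg, mod, alpha = 5.6 / L, kmax = 10)
  madelung <- -U * a / (4 * lB)
  expect_equal(madelung, 1.7476, tolerance = 1e-3)
})

test_that("Ewald energy is independent of the splitting parameter", {
  mod <- rpm11()
  cfg <- configuration(rbind(c(0, 0, 0), c(4, 1, 0), c(10, 10, 10),
                             c(14, 9, 10)), c("M", "X", "M", "X"), 30)
  E <- vapply(c(0.2, 0.3, 0.4), function(a)
    ewald_energy(cfg, mod, alpha = a, kmax = 14, real_cutoff = 15),
    numeric(1))
  expect_lt(max(abs(E - E[1])) / abs(E[1]), 1e-4)
})

test_that("non-electroneutral configurations are rejected", {
  mod <- rpm11()
  cfg <- configuration(rbind(c(0, 0, 0), c(3, 0, 0)), c("M", "M"), 50)
  expect_error(ewald_energy(cfg, mod), "electroneutral")
  expect_error(run_mc(mod, mc_config(c(M = 4, X = 2), 40)),
               "electroneutral")
})

test_that("near-ideal gas: zero excess energy and phi of one", {
  hs <- pm_model(list(pm_species("A", 0, 0.5)))
  cfg <- mc_config(c(A = 64), box_length = 60, max_displacement = 10,
                   n_equilibration = 1e4, n_production = 4e5, seed = 3)
  res <- run_mc(hs, cfg)
  expect_equal(res$energy_per_particle, 0)
  phi <- mc_osmotic_coefficient(res)
  expect_equal(phi$phi, 1.0, tolerance = 0.01)
})

test_that("identical seeds give identical trajectories", {
  mod <- rpm11()
  cfg <- mc_config(c(M = 8, X = 8), box_length = 30, n_equilibration = 1e3,
                   n_production = 2e4, seed = 7)
  r1 <- run_mc(mod, cfg)
  r2 <- run_mc(mod, cfg)
  expect_identical(r1$block_energy, r2$block_energy)
  expect_identical(r1$snapshots[[1]]$positions, r2$snapshots[[1]]$positions)
  expect_identical(r1$acceptance_rate, r2$acceptance_rate)
})

test_that("incremental energy bookkeeping tracks full recomputation", {
  mod <- rpm22()
  cfg <- mc_config(c(M = 16, X = 16), box_length = 40, n_equilibration = 1e4,
                   n_production = 1e5, seed = 5)
  res <- run_mc(mod, cfg)
  expect_lt(res$max_energy_drift, 1e-6)
})

test_that("acceptance rate decreases as the step size grows", {
  hs <- pm_model(list(pm_species("A", 0, 1)))
  L <- (128 / (0.2 * 6 / pi))^(1 / 3)
  acc <- vapply(c(0.3, 1, 3), function(dx) {
    cfg <- mc_config(c(A = 128), box_length = L, max_displacement = dx,
                     n_equilibration = 5e3, n_production = 5e4, seed = 2)
    run_mc(hs, cfg)$acceptance_rate
  }, numeric(1))
  expect_true(all(diff(acc) < 0))
})

test_that("hard cores are never violated in sampled snapshots", {
  hs <- pm_model(list(pm_species("A", 0, 2)))
  cfg <- mc_config(c(A = 64), box_length = 20, max_displacement = 1,
                   n_equilibration = 1e4, n_production = 1e5, seed = 9)
  res <- run_mc(hs, cfg)
  rdf <- compute_rdf(res$snapshots, "A", "A", bin_width = 0.05)
  mids <- (rdf$bin_edges[-1] + head(rdf$bin_edges, -1)) / 2
  expect_true(all(rdf$counts[mids < 2 - 0.025] == 0))
  # and the internal accumulator agrees with the analysis-layer RDF
  mcg <- mc_rdf(res, "A", "A")
  snap_r <- ionpair:::.pair_distances(res$snapshots[[1]]$positions,
                                      res$snapshots[[1]]$positions, 20)
  expect_true(min(snap_r[upper.tri(snap_r)]) >= 2)
  expect_equal(length(mcg$g), length(mcg$counts))
})

test_that("Metropolis acceptance satisfies detailed balance exactly", {
  set.seed(31)
  d <- stats::rnorm(50, sd = 3)
  a_fwd <- exchange_acceptance(d)
  a_rev <- exchange_acceptance(-d)
  expect_equal(a_fwd / a_rev, exp(-d), tolerance = 1e-14)
  expect_identical(exchange_acceptance(0), 1)
  expect_equal(exchange_acceptance(log(2)), 0.5)
  expect_equal(exchange_acceptance(Inf), 0)
  expect_true(all(exchange_acceptance(-abs(d)) == 1))
})

test_that("mc_config validates box and block constraints", {
  expect_error(mc_config(c(A = 10), 40, real_cutoff = 30), "real_cutoff")
  expect_error(mc_config(c(A = 10), 40, n_blocks = 5), "blocks")
  mod <- rpm22()
  expect_error(run_mc(mod, mc_config(c(M = 2, X = 2), 8)), "box_length")
})
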