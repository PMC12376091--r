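test_that("random configurations respect hard cores and the seed", {
  hs <- pm_model(list(pm_species("A", 0, 1)))
  st <- pm_state(hs, c(A = 0.05 * 6 / pi))
  L <- (100 / st$number_densities[["A"]])^(1 / 3)
  c1 <- gen_random_config(hs, st, L, seed = 1)
  expect_equal(nrow(c1$positions), 100)
  r <- ionpair:::.pair_distances(c1$positions, c1$positions, L)
  expect_true(min(r[upper.tri(r)]) >= 1)
  c2 <- gen_random_config(hs, st, L, seed = 1)
  expect_identical(c1$positions, c2$positions)
  c3 <- gen_random_config(hs, st, L, seed = 2)
  expect_false(identical(c1$positions, c3$positions))
  # zero density gives an empty configuration
  empty <- gen_random_config(hs, pm_state(hs, c(A = 0)), 20)
  expect_equal(nrow(empty$positions), 0)
})

test_that("planted CIP/SIP counts round-trip through classification", {
  for (n_cip in c(0L, 1L, 3L, 8L)) for (n_sip in c(0L, 3L)) {
    sp <- paired_spec(n_cations = 12, n_anions = 12, n_waters = 6,
                      box_length = 100, n_cip = n_cip, n_sip = n_sip,
                      r_contact = 3.0, r_sip_gap = 2.6,
                      seed = 10 + n_cip + n_sip)
    out <- gen_paired_config(sp)
    cl <- classify_pairs(out$config, "M", "S", r_cip = 4.0, r_sip = 6.0)
    expect_equal(unname(cl$counts[c("cip", "sip")]),
                 as.integer(c(n_cip, n_sip)),
                 info = sprintf("n_cip=%d n_sip=%d", n_cip, n_sip))
  }
})

test_that("without planted contacts there is no short-range pair density", {
  sp <- paired_spec(n_cations = 6, n_anions = 6, n_waters = 0,
                    box_length = 80, n_cip = 0, n_sip = 0, seed = 5)
  out <- gen_paired_config(sp)
  cl <- classify_pairs(out$config, "M", "S", r_cip = 4, r_sip = 6)
  expect_equal(unname(cl$counts[c("cip", "sip")]), c(0L, 0L))
  expect_gt(min(cl$pairs$r), 6)
})

test_that("tetrahedral anions carry four oxygens at the S-O distance", {
  sp <- paired_spec(n_cations = 2, n_anions = 2, n_waters = 0,
                    box_length = 50, n_cip = 1, n_sip = 0, seed = 3,
                    tetrahedral_anions = TRUE)
  out <- gen_paired_config(sp)
  expect_equal(sum(out$config$species == "SO"), 8)
  si <- which(out$config$species == "S")
  oi <- which(out$config$species == "SO")
  r <- ionpair:::.pair_distances(out$config$positions[si, , drop = FALSE],
                                 out$config$positions[oi, , drop = FALSE],
                                 50)
  # each S has its own four oxygens at exactly 1.52 A
  expect_equal(sort(apply(r, 2, min)), rep(1.52, 8), tolerance = 1e-12)
})

test_that("induced dipoles follow the Coulomb field of the ions", {
  mod <- pm_model(list(pm_species("M", 2, 2.6), pm_species("S", -2, 4.6),
                       pm_species("W", 0, 2.8)))
  L <- 40
  mk <- function(rw) configuration(rbind(c(20, 20, 20),
                                         c(20 + rw, 20, 20)),
                                   c("M", "W"), L)
  spec <- dipole_spec(alpha_prime = 1.0, water_species = "W")
  d1 <- gen_dipole_field(mk(4), spec, mod)
  d2 <- gen_dipole_field(mk(8), spec, mod)
  mu1 <- sqrt(sum(d1$dipoles[2, ]^2))
  mu2 <- sqrt(sum(d2$dipoles[2, ]^2))
  # |mu| ~ q/r^2: doubling the distance quarters the dipole
  expect_equal(mu1 / mu2, 4, tolerance = 1e-12)
  # |mu| doubles with the ion charge
  mono <- scale_charges(mod, 0.5)
  dm <- gen_dipole_field(mk(4), spec, mono)
  expect_equal(mu1 / sqrt(sum(dm$dipoles[2, ]^2)), 2, tolerance = 1e-12)
  # no ions: all dipoles zero
  lone <- configuration(rbind(c(1, 1, 1)), "W", L)
  expect_true(all(gen_dipole_field(lone, spec, mod)$dipoles == 0))
})

test_that("dipole fields superpose exactly", {
  mod <- pm_model(list(pm_species("M", 2, 2.6), pm_species("S", -2, 4.6),
                       pm_species("W", 0, 2.8)))
  L <- 40
  spec <- dipole_spec(alpha_prime = 1.0, water_species = "W")
  w <- c(20, 20, 20)
  ion1 <- c(24, 20, 20); ion2 <- c(20, 26, 21)
  both <- gen_dipole_field(configuration(rbind(ion1, ion2, w),
                                         c("M", "M", "W"), L), spec, mod)
  one <- gen_dipole_field(configuration(rbind(ion1, w), c("M", "W"), L),
                          spec, mod)
  two <- gen_dipole_field(configuration(rbind(ion2, w), c("M", "W"), L),
                          spec, mod)
  expect_equal(both$dipoles[3, ], one$dipoles[2, ] + two$dipoles[2, ],
               tolerance = 1e-12)
})

test_that("shell polarization is stronger for small divalent cations", {
  ## one cation solvated by a shell of waters plus bulk waters, for the
  ## divalent small-ion (q=2, d=2.6) and monovalent large-ion (q=1,
  ## d=3.6) variants; shared geometry except the contact distance
  build <- function(d_cat, charge) {
    mod <- pm_model(list(pm_species("M", charge, d_cat),
                         pm_species("S", -charge, 4.6),
                         pm_species("W", 0, 2.8)))
    L <- 50
    center <- c(25, 25, 25)
    rshell <- (d_cat + 2.8) / 2 + 0.2
    set.seed(6)
    shell <- t(vapply(1:6, function(i) {
      u <- stats::rnorm(3); center + u / sqrt(sum(u^2)) * rshell
    }, numeric(3)))
    bulk <- matrix(runif(3 * 30, 0, 50), 30, 3)
    keep <- sqrt(colSums((t(bulk) - center)^2)) > 12
    pos <- rbind(center, shell, bulk[keep, ])
    cfg <- configuration(pos, c("M", rep("W", nrow(pos) - 1)), L)
    gen_dipole_field(cfg, dipole_spec(alpha_prime = 1.0,
                                      water_species = "W"), mod)
  }
  dmu_div <- delta_mu_ind(build(2.6, 2), "M", "W", cutoff = 4.5)
  dmu_mono <- delta_mu_ind(build(3.6, 1), "M", "W", cutoff = 4.5)
  expect_gt(dmu_div, 0)
  expect_gt(dmu_div, dmu_mono)
})
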