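test_that("distance-window classification recovers planted pairs", {
  sp <- paired_spec(n_cations = 8, n_anions = 8, n_waters = 10,
                    box_length = 70, n_cip = 3, n_sip = 5,
                    r_contact = 3.0, r_sip_gap = 2.6, seed = 4)
  out <- gen_paired_config(sp)
  cl <- classify_pairs(out$config, "M", "S", r_cip = 4.0, r_sip = 6.0)
  expect_equal(unname(cl$counts["cip"]), 3L)
  expect_equal(unname(cl$counts["sip"]), 5L)
  # counts partition all cation-anion pairs
  expect_equal(sum(cl$counts), 8L * 8L)
})

test_that("ions beyond the SIP window are all unpaired", {
  cfg <- configuration(rbind(c(5, 5, 5), c(25, 25, 25)), c("M", "S"), 60)
  cl <- classify_pairs(cfg, "M", "S", 4, 6)
  expect_equal(unname(cl$counts), c(0L, 0L, 1L))
})

test_that("one anion in contact with two cations counts as two CIPs", {
  cfg <- configuration(rbind(c(10, 10, 10),            # anion
                             c(13, 10, 10), c(7, 10, 10)),  # two cations
                       c("S", "M", "M"), 40)
  cl <- classify_pairs(cfg, "M", "S", r_cip = 4, r_sip = 6)
  expect_equal(unname(cl$counts["cip"]), 2L)
})

test_that("classification window must be ordered", {
  cfg <- configuration(matrix(1, 1, 3), "M", 10)
  expect_error(classify_pairs(cfg, "M", "S", 5, 3), "r_cip < r_sip")
})

test_that("shell membership applies a strict distance cutoff once per water", {
  cfg <- configuration(rbind(c(10, 10, 10),
                             c(13.1, 10, 10),   # 3.1 A: inside
                             c(13.3, 10, 10),   # 3.3 A: outside
                             c(6.9, 10, 10)),   # 3.1 A from the same cation
                       c("M", "W", "W", "W"), 40)
  m <- shell_membership(cfg, "M", "W", cutoff = 3.2)
  expect_identical(m, c(TRUE, FALSE, TRUE))
  # no centres: all out; no partners: empty mask
  cfg2 <- configuration(rbind(c(1, 1, 1)), "W", 40)
  expect_identical(shell_membership(cfg2, "M", "W"), FALSE)
  cfg3 <- configuration(rbind(c(1, 1, 1)), "M", 40)
  expect_length(shell_membership(cfg3, "M", "W"), 0)
})

test_that("delta_mu_ind measures the planted shell-bulk contrast", {
  mk <- function(mu_shell, mu_bulk) {
    pos <- rbind(c(10, 10, 10), c(12, 10, 10), c(30, 30, 30), c(35, 30, 30))
    dip <- rbind(c(0, 0, 0), c(mu_shell, 0, 0), c(mu_bulk, 0, 0),
                 c(0, mu_bulk, 0))
    configuration(pos, c("M", "W", "W", "W"), 60, dipoles = dip)
  }
  expect_equal(delta_mu_ind(mk(0.65, 0.65), "M", "W", cutoff = 3.2), 0)
  expect_equal(delta_mu_ind(mk(1.65, 0.65), "M", "W", cutoff = 3.2), 1.0)
  nod <- configuration(rbind(c(1, 1, 1)), "W", 10)
  expect_error(delta_mu_ind(nod, "M", "W"), "no induced dipoles")
})

test_that("Drude displacement converts to debye with q*d", {
  expect_equal(induced_dipole_from_drude(c(0, 0, 0), -1), c(0, 0, 0))
  mu <- induced_dipole_from_drude(c(0.1, 0, 0), -1)
  expect_equal(sqrt(sum(mu^2)), 0.48032047, tolerance = 1e-7)
  expect_equal(induced_dipole_from_drude(c(0.2, 0, 0), -1), 2 * mu)
})

test_that("polarization energy laws: quadratic field, quartic distance", {
  expect_identical(upol_field(3, c(0, 0, 0)), 0)
  u1 <- upol_field(3, c(0.1, 0.2, 0))
  expect_equal(upol_field(3, 2 * c(0.1, 0.2, 0)), 4 * u1)
  expect_lt(u1, 0)
  expect_error(upol_field(-1, 1), "alpha")

  expect_identical(upol_point_charge(5, 0, 3), 0)
  u <- upol_point_charge(5, 2, 4)
  expect_equal(upol_point_charge(5, 2, 2), 16 * u)
  expect_equal(upol_point_charge(5, 2, 4) / upol_point_charge(5, 1, 4), 4)
  expect_lt(u, 0)
  expect_error(upol_point_charge(5, 2, 0), "distance")
  # field-route consistency: -(alpha/2)E^2 with E = q/r^2 gives half the
  # printed point-charge expression
  lB <- bjerrum_length(78.36, 298.15)
  q <- 2; r <- 3.5; ap <- 5
  expect_equal(upol_field(ap * lB, q / r^2),
               0.5 * upol_point_charge(ap, q, r))
  expect_equal(upol_field(ap * lB, q / r^2),
               upol_point_charge(ap, q, r, half = TRUE))
})

test_that("lambda mixing is an exact affine combination", {
  expect_identical(mixed_energy(0, 10, 20), 10)
  expect_identical(mixed_energy(1, 10, 20), 20)
  expect_identical(mixed_energy(0.5, 10, 20), 15)
  expect_error(mixed_energy(1.2, 1, 2), "lambda")
})
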