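## Point-polarizability energetics and the lambda-mixed Hamiltonian
## used by Hamiltonian replica exchange.
##
## Internal electrostatic units: charges in e, distances in angstrom,
## energies in k_B*T.  The electric field of a point charge q at
## distance r is q/r^2 in units of e/A^2; a polarizability alpha in
## k_B*T A^4/e^2 then gives energies directly in k_B*T.  The
## polarizability volume alpha' (A^3) maps onto these units as
## alpha = alpha' * l_B.

#' Polarization energy of a point polarizability in a field
#'
#' U = -(alpha/2) |E|^2.  Always non-positive: polarization lowers the
#' total interaction energy.
#'
#' @param alpha polarizability in k_B*T A^4/e^2 (alpha' * l_B for a
#'   polarizability volume alpha' in A^3).
#' @param field electric field vector or magnitude in e/A^2.
#' @return beta-energy (k_B*T units), <= 0.
#' @export
upol_field <- function(alpha, field) {
  if (!is.finite(alpha) || alpha < 0) stop("'alpha' must be >= 0")
  E2 <- sum(field^2)
  -alpha / 2 * E2
}

#' Polarization energy of a point polarizability near a point charge
#'
#' The closed form U = -alpha' q^2 / (4 pi eps0 r^4), evaluated in
#' internal units as -alpha' q^2 l_B / r^4.  Note that inserting the
#' point-charge field E = q/r^2 into \code{\link{upol_field}} gives half
#' this value; both conventions circulate, so the half-consistent
#' variant is available via \code{half = TRUE}.
#'
#' @param alpha_prime polarizability volume in A^3 (>= 0).
#' @param charge source charge in e.
#' @param distance separation in angstrom (> 0).
#' @param bjerrum Bjerrum length of the medium in angstrom; the default
#'   7.152 A corresponds to water at 25 C.
#' @param half if TRUE, apply the factor 1/2 that makes the expression
#'   consistent with -(alpha/2) E^2.
#' @return beta-energy (k_B*T units); strictly negative for charge != 0,
#'   scaling as 1/r^4 and q^2.
#' @export
upol_point_charge <- function(alpha_prime, charge, distance,
                              bjerrum = bjerrum_length(78.36, 298.15),
                              half = FALSE) {
  if (any(!is.finite(distance) | distance <= 0))
    stop("'distance' must be > 0")
  if (!is.finite(alpha_prime) || alpha_prime < 0)
    stop("'alpha_prime' must be >= 0")
  u <- -alpha_prime * charge^2 * bjerrum / distance^4
  if (half) u / 2 else u
}

#' Induced dipole of a Drude oscillator
#'
#' mu = q * d for a shell particle of charge q displaced by d from its
#' anchor, converted from e*angstrom to debye.
#'
#' @param shell_displacement displacement vector (or matrix of row
#'   vectors) in angstrom.
#' @param shell_charge Drude shell charge in e.
#' @return induced dipole vector(s) in debye.
#' @export
induced_dipole_from_drude <- function(shell_displacement, shell_charge) {
  shell_charge * shell_displacement * .const$eA_to_D
}

#' Lambda-mixed Hamiltonian
#'
#' U = (1 - lambda) U_A + lambda U_B, the energy interpolation between
#' two Hamiltonian end states used by replica exchange (lambda = 0 is
#' the A state, lambda = 1 the B state).
#'
#' @param lambda mixing parameter in [0, 1].
#' @param U_A,U_B end-state beta-energies.
#' @return mixed beta-energy.
#' @export
mixed_energy <- function(lambda, U_A, U_B) {
  if (any(!is.finite(lambda) | lambda < 0 | lambda > 1))
    stop("'lambda' must lie in [0, 1]")
  (1 - lambda) * U_A + lambda * U_B
}
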