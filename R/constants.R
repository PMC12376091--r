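## Physical constants (CODATA 2018) and internal unit conventions.
##
## Internal units throughout the package:
##   length  : angstrom (A)
##   charge  : elementary charges (e), fractional values allowed
##   energy  : k_B * T at the model temperature ("beta-energy")
##   dipole  : debye (D)

.const <- list(
  e_C       = 1.602176634e-19,   # elementary charge, C
  eps0      = 8.8541878128e-12,  # vacuum permittivity, F/m
  kB        = 1.380649e-23,      # Boltzmann constant, J/K
  N_A       = 6.02214076e23,     # Avogadro constant, 1/mol
  eA_to_D   = 4.8032047,         # 1 e*A in debye
  M_water   = 0.018015,          # molar mass of water, kg/mol
  rho_water = 997.0              # density of water at 25 C, kg/m^3
)

## Error functions via the normal CDF (base R has no erf/erfc).
.erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
.erfc <- function(x) 2 * stats::pnorm(-x * sqrt(2))

#' Bjerrum length of a dielectric continuum
#'
#' Distance at which two unit charges embedded in a medium of relative
#' permittivity \code{epsilon_r} interact with thermal energy k_B T:
#' \eqn{l_B = e^2 / (4 \pi \epsilon_0 \epsilon_r k_B T)}.
#'
#' @param model a \code{\link{pm_model}}, or a relative permittivity if
#'   \code{temperature} is also given.
#' @param temperature temperature in kelvin (only when \code{model} is a
#'   bare permittivity).
#' @return Bjerrum length in angstrom.
#' @examples
#' bjerrum_length(78.36, 298.15)  # about 7.15 A: water at 25 C
#' @export
bjerrum_length <- function(model, temperature = NULL) {
  if (inherits(model, "pm_model")) {
    eps_r <- model$epsilon_r
    temp <- model$temperature
  } else {
    eps_r <- model
    temp <- temperature
    if (is.null(temp)) stop("temperature required when 'model' is a permittivity")
  }
  with(.const, e_C^2 / (4 * pi * eps0 * eps_r * kB * temp) * 1e10)
}
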