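## Primitive-model electrolyte definition: species, model container,
## pair potential, charge scaling and molality <-> number-density maps.

#' Define an ionic (or neutral) species
#'
#' @param name species label, unique within a model.
#' @param charge charge in elementary charges; fractional values (e.g.
#'   +1.5 for a charge-scaled variant) are allowed.
#' @param diameter hard-sphere diameter d_ii in angstrom; must be > 0.
#' @param polarizability_volume polarizability volume alpha' in cubic
#'   angstrom (0 = nonpolarizable site).
#' @return an object of class \code{pm_species}.
#' @export
pm_species <- function(name, charge, diameter, polarizability_volume = 0) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("'name' must be a non-empty string")
  if (!is.finite(diameter) || diameter <= 0)
    stop("'diameter' must be > 0 (got ", diameter, ")")
  if (!is.finite(charge))
    stop("'charge' must be finite")
  if (!is.finite(polarizability_volume) || polarizability_volume < 0)
    stop("'polarizability_volume' must be >= 0")
  structure(list(name = name, charge = charge, diameter = diameter,
                 polarizability_volume = polarizability_volume),
            class = "pm_species")
}

#' Build a primitive-model electrolyte
#'
#' The primitive model represents ions as charged hard spheres in a
#' dielectric continuum: the pair potential is an infinite hard core for
#' r < d_ij plus the Coulomb interaction q_i q_j l_B / r (in units of
#' k_B T) outside the core.  Distances of closest approach d_ij are
#' filled in by the additivity rule d_ij = (d_ii + d_jj)/2.
#'
#' @param species a list of \code{\link{pm_species}} objects.
#' @param epsilon_r relative permittivity of the continuum (> 1);
#'   78.36 corresponds to pure water at 25 C.
#' @param temperature temperature in kelvin.
#' @return an object of class \code{pm_model} with elements
#'   \code{species}, \code{epsilon_r}, \code{temperature},
#'   \code{closest_approach} (symmetric d_ij matrix, angstrom),
#'   \code{charge} and \code{diameter} vectors.
#' @examples
#' salt <- pm_model(list(pm_species("M", 2, 2.6), pm_species("X", -2, 4.6)),
#'                  epsilon_r = 78.36, temperature = 298.15)
#' salt$closest_approach
#' @export
pm_model <- function(species, epsilon_r = 78.36, temperature = 298.15) {
  if (inherits(species, "pm_species")) species <- list(species)
  if (length(species) < 1L) stop("at least one species required")
  ok <- vapply(species, inherits, logical(1), what = "pm_species")
  if (!all(ok)) stop("'species' must be a list of pm_species objects")
  nm <- vapply(species, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("species names must be unique: ",
                              paste(nm[duplicated(nm)], collapse = ", "))
  if (!is.finite(epsilon_r) || epsilon_r <= 1)
    stop("'epsilon_r' must be > 1 (got ", epsilon_r, ")")
  if (!is.finite(temperature) || temperature <= 0)
    stop("'temperature' must be > 0 (got ", temperature, ")")
  d <- vapply(species, `[[`, numeric(1), "diameter")
  q <- vapply(species, `[[`, numeric(1), "charge")
  dij <- outer(d, d, function(a, b) (a + b) / 2)
  dimnames(dij) <- list(nm, nm)
  m <- structure(list(species = species,
                      epsilon_r = epsilon_r,
                      temperature = temperature,
                      closest_approach = dij,
                      charge = stats::setNames(q, nm),
                      diameter = stats::setNames(d, nm)),
                 class = "pm_model")
  m
}

#' @export
print.pm_model <- function(x, ...) {
  cat("Primitive-model electrolyte\n")
  cat(sprintf("  epsilon_r = %.4g, T = %.6g K, Bjerrum length = %.4f A\n",
              x$epsilon_r, x$temperature, bjerrum_length(x)))
  df <- data.frame(name = names(x$charge), charge = unname(x$charge),
                   diameter_A = unname(x$diameter),
                   alpha_prime_A3 = vapply(x$species, `[[`, numeric(1),
                                           "polarizability_volume"))
  print(df, row.names = FALSE)
  cat("  closest approach d_ij (A):\n")
  print(round(x$closest_approach, 4))
  invisible(x)
}

.species_index <- function(model, i) {
  nm <- names(model$charge)
  if (is.character(i)) {
    k <- match(i, nm)
    if (anyNA(k)) stop("unknown species: ", paste(i[is.na(k)], collapse = ", "))
    return(k)
  }
  i <- as.integer(i)
  if (any(i < 1L | i > length(nm))) stop("species index out of range")
  i
}

#' Primitive-model pair potential
#'
#' Beta-energy (units of k_B T) of species pair (i, j) at separation r:
#' \code{Inf} inside the hard core (r < d_ij), the bare Coulomb term
#' q_i q_j l_B / r outside, identically zero for two neutral species.
#'
#' @param model a \code{\link{pm_model}}.
#' @param i,j species names or indices.
#' @param r separation(s) in angstrom, > 0; vectorised.
#' @return beta-energy, with \code{Inf} as the hard-core sentinel.
#' @export
pair_potential <- function(model, i, j, r) {
  stopifnot(inherits(model, "pm_model"))
  i <- .species_index(model, i); j <- .species_index(model, j)
  if (any(!is.finite(r) | r <= 0)) stop("'r' must be positive and finite")
  dij <- model$closest_approach[i, j]
  u <- model$charge[[i]] * model$charge[[j]] * bjerrum_length(model) / r
  u[r < dij] <- Inf
  u
}

#' Scale all species charges by a common factor
#'
#' Produces the charge-scaled variant of a model (e.g. halving a +/-2
#' salt to +/-1, or scaling to three-quarters for a +/-1.5 variant);
#' diameters, permittivity and temperature are untouched.
#'
#' @param model a \code{\link{pm_model}}.
#' @param factor positive multiplier applied to every charge.
#' @return a new \code{pm_model}.
#' @export
scale_charges <- function(model, factor) {
  stopifnot(inherits(model, "pm_model"))
  if (!is.finite(factor) || factor <= 0)
    stop("'factor' must be > 0 (got ", factor, ")")
  sp <- lapply(model$species, function(s) {
    s$charge <- s$charge * factor
    s
  })
  pm_model(sp, epsilon_r = model$epsilon_r, temperature = model$temperature)
}

#' Ionic state: per-species number densities
#'
#' @param model a \code{\link{pm_model}}.
#' @param number_densities named or positional vector of number densities
#'   in particles per cubic angstrom, one per model species.
#' @param molality optional provenance field (mol salt per kg solvent).
#' @return an object of class \code{pm_state}.
#' @export
pm_state <- function(model, number_densities, molality = NULL) {
  stopifnot(inherits(model, "pm_model"))
  nm <- names(model$charge)
  rho <- number_densities
  if (!is.null(names(rho))) rho <- rho[nm]
  if (length(rho) != length(nm) || anyNA(rho))
    stop("need one density per model species (", paste(nm, collapse = ", "), ")")
  if (any(rho < 0)) stop("densities must be >= 0")
  rho <- stats::setNames(as.numeric(rho), nm)
  qsum <- sum(model$charge * rho)
  scale <- sum(abs(model$charge) * rho)
  if (scale > 0 && abs(qsum) / scale > 1e-12)
    stop("state is not electroneutral: sum q_i rho_i = ", qsum)
  structure(list(number_densities = rho, molality = molality),
            class = "pm_state")
}

#' Convert salt molality to an electroneutral ionic state
#'
#' Number densities assume a pure-water solvent of density 997.0 kg/m^3
#' and zero solute partial volume, so that one kilogram of solvent
#' occupies 1/997.0 m^3 regardless of the amount of salt dissolved.
#'
#' @param model a \code{\link{pm_model}}.
#' @param molality salt molality in mol per kg of solvent (>= 0).
#' @param stoichiometry named integer vector of ions released per formula
#'   unit (e.g. \code{c(M = 1, X = 1)} for MgSO4-like 1:1 dissociation);
#'   must be electroneutral against the model charges.  Species absent
#'   from the stoichiometry get density zero.
#' @param solvent_density solvent mass density in kg/m^3.
#' @return a \code{\link{pm_state}}.
#' @export
molality_to_state <- function(model, molality, stoichiometry,
                              solvent_density = .const$rho_water) {
  stopifnot(inherits(model, "pm_model"))
  if (!is.finite(molality) || molality < 0) stop("'molality' must be >= 0")
  nm <- names(model$charge)
  if (is.null(names(stoichiometry)))
    stop("'stoichiometry' must be a named vector of per-species counts")
  k <- .species_index(model, names(stoichiometry))
  nu <- numeric(length(nm)); nu[k] <- stoichiometry
  if (abs(sum(nu * model$charge)) > 1e-12 * max(1, sum(abs(nu * model$charge))))
    stop("stoichiometry is not electroneutral for the model charges")
  ## rho_i [A^-3] = nu_i * m [mol/kg] * N_A [1/mol] * rho_w [kg/m^3] * 1e-30
  rho <- nu * molality * .const$N_A * solvent_density * 1e-30
  pm_state(model, stats::setNames(rho, nm), molality = molality)
}

#' Recover the salt molality from an ionic state
#'
#' Inverse of \code{\link{molality_to_state}} under the same
#' solvent-density convention.
#'
#' @param state a \code{\link{pm_state}}.
#' @param stoichiometry the per-formula-unit ion counts used to build it.
#' @param solvent_density solvent mass density in kg/m^3.
#' @return molality in mol/kg.
#' @export
state_to_molality <- function(state, stoichiometry,
                              solvent_density = .const$rho_water) {
  stopifnot(inherits(state, "pm_state"))
  nm <- names(stoichiometry)
  rho <- state$number_densities[nm]
  if (anyNA(rho)) stop("stoichiometry names not found in state")
  m <- rho / (stoichiometry * .const$N_A * solvent_density * 1e-30)
  if (length(m) > 1 && diff(range(m)) > 1e-9 * max(m))
    warning("state densities inconsistent with the given stoichiometry")
  mean(m)
}

#' Molality of a simulation box from its composition
#'
#' Salt molality implied by counting ion pairs against water molecules:
#' m = n_pairs / (n_waters * M_water), with M_water = 0.018015 kg/mol.
#' Twelve ion pairs per 665 waters, the composition of a typical
#' explicit-solvent box, gives 1.00 mol/kg.
#'
#' @param n_pairs number of salt formula units in the box.
#' @param n_waters number of water molecules.
#' @return molality in mol/kg.
#' @export
composition_molality <- function(n_pairs, n_waters) {
  stopifnot(n_pairs >= 0, n_waters > 0)
  n_pairs / (n_waters * .const$M_water)
}

#' Cubic box edge implied by a solution composition and mass density
#'
#' Edge length of the cube that holds \code{n_waters} water molecules and
#' \code{n_pairs} salt formula units at the given solution mass density.
#'
#' @param n_pairs salt formula units.
#' @param n_waters water molecules.
#' @param salt_molar_mass molar mass of the salt in g/mol (default
#'   120.366, anhydrous MgSO4).
#' @param density solution mass density in g/cm^3 (default 1.10, a
#'   1 mol/kg magnesium sulfate solution at 25 C).
#' @return box edge in angstrom.
#' @export
solution_box_edge <- function(n_pairs, n_waters,
                              salt_molar_mass = 120.366, density = 1.10) {
  stopifnot(n_pairs >= 0, n_waters >= 0, density > 0)
  mass_g <- (n_waters * .const$M_water * 1e3 + n_pairs * salt_molar_mass) /
    .const$N_A
  vol_A3 <- mass_g / density * 1e24
  vol_A3^(1 / 3)
}
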