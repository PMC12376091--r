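## Synthetic-data generators: random hard-sphere configurations,
## paired-ion configurations with planted CIP/SIP truth, field-aligned
## induced dipoles, and noisy osmotic-coefficient curves.  Everything
## is bit-deterministic under a fixed seed.

#' Random non-overlapping configuration for a model state
#'
#' Uniform random sequential insertion honouring every hard-core
#' distance of the model; particle counts are round(rho_i * V).
#'
#' @param model a \code{\link{pm_model}}.
#' @param state a \code{\link{pm_state}}.
#' @param box_length cubic box edge in angstrom.
#' @param seed integer seed.
#' @return a \code{\link{configuration}}.
#' @export
gen_random_config <- function(model, state, box_length, seed = 1L) {
  stopifnot(inherits(model, "pm_model"), inherits(state, "pm_state"))
  counts <- round(state$number_densities * box_length^3)
  nm <- names(model$charge)
  species_idx <- rep(seq_along(nm), counts)
  set.seed(seed)
  if (!length(species_idx))
    return(configuration(matrix(0, 0, 3), character(0), box_length))
  pos <- .place_random(species_idx, model$closest_approach, box_length,
                       max_attempts = 1e6)
  configuration(pos, nm[species_idx], box_length)
}

#' Specification for a paired-ion configuration
#'
#' @param n_cations,n_anions,n_waters particle counts.
#' @param box_length cubic box edge in angstrom.
#' @param n_cip planted contact ion pairs; distributed round-robin over
#'   the cations, so values above \code{n_cations} plant multi-anion
#'   contact clusters (aggregates).  Must not exceed \code{n_anions}.
#' @param n_sip planted solvent-shared arrangements
#'   (cation-water-anion, collinear).
#' @param r_contact cation-anion distance of planted CIPs, angstrom.
#' @param r_sip_gap ion-water distance in planted SIPs; the planted
#'   cation-anion separation is 2 * r_sip_gap.
#' @param seed integer seed.
#' @param cation,anion,water species labels used in the output.
#' @param tetrahedral_anions if TRUE, each anion becomes a central "S"
#'   site plus four tetrahedral oxygen sites (label
#'   \code{paste0(anion, "O")}) at S-O 1.52 A.
#' @return an object of class \code{paired_spec}.
#' @export
paired_spec <- function(n_cations, n_anions, n_waters, box_length,
                        n_cip, n_sip, r_contact = 3.5, r_sip_gap = 2.6,
                        seed = 1L, cation = "M", anion = "S", water = "W",
                        tetrahedral_anions = FALSE) {
  if (n_cip + n_sip > n_anions)
    stop("planted pairings need ", n_cip + n_sip, " anions, have ", n_anions)
  if (min(n_cip, n_cations) + n_sip > n_cations)
    stop("planted pairings need more cations than available")
  if (n_sip > n_waters) stop("each planted SIP needs a water")
  structure(list(n_cations = n_cations, n_anions = n_anions,
                 n_waters = n_waters, box_length = box_length,
                 n_cip = n_cip, n_sip = n_sip, r_contact = r_contact,
                 r_sip_gap = r_sip_gap, seed = as.integer(seed),
                 cation = cation, anion = anion, water = water,
                 tetrahedral_anions = tetrahedral_anions),
            class = "paired_spec")
}

.rand_unit <- function() {
  repeat {
    v <- stats::runif(3, -1, 1)
    n2 <- sum(v^2)
    if (n2 > 1e-6 && n2 <= 1) return(v / sqrt(n2))
  }
}

#' Generate a configuration with planted CIP/SIP truth
#'
#' Plants exactly \code{n_cip} cation-anion contacts at
#' \code{r_contact} and \code{n_sip} collinear cation-water-anion
#' arrangements with ion-water spacing \code{r_sip_gap}; all remaining
#' particles are dispersed with every unplanted cation-anion distance
#' kept above twice the SIP separation, so a distance-window classifier
#' recovers the planted counts exactly.
#'
#' @param spec a \code{\link{paired_spec}}.
#' @return list with \code{config} (a \code{\link{configuration}}) and
#'   \code{truth} (planted pair table and counts).
#' @export
gen_paired_config <- function(spec) {
  stopifnot(inherits(spec, "paired_spec"))
  set.seed(spec$seed)
  L <- spec$box_length
  r_pair_max <- 2 * spec$r_sip_gap
  clear <- r_pair_max + 2.0          # unplanted ions stay beyond this
  ## build units: each unit is a small rigid group of particles
  units <- list()
  ## round-robin CIP assignment over cations
  cip_cation <- rep(seq_len(spec$n_cations), length.out = spec$n_cip)
  if (spec$n_cip > 0) {
    for (ci in unique(cip_cation)) {
      n_at <- sum(cip_cation == ci)
      dirs <- list()
      for (a in seq_len(n_at)) {
        repeat {
          u <- .rand_unit()
          ok <- all(vapply(dirs, function(v)
            sqrt(sum((u - v)^2)) * spec$r_contact > 2.0, logical(1)))
          if (ok) break
        }
        dirs[[a]] <- u
      }
      rel <- rbind(c(0, 0, 0),
                   t(vapply(dirs, function(u) u * spec$r_contact,
                            numeric(3))))
      units[[length(units) + 1L]] <-
        list(rel = rel,
             species = c(spec$cation, rep(spec$anion, n_at)),
             role = c("cip_cation", rep("cip_anion", n_at)))
    }
  }
  n_cat_used <- length(unique(cip_cation))
  n_an_used <- spec$n_cip
  for (s in seq_len(spec$n_sip)) {
    u <- .rand_unit()
    rel <- rbind(c(0, 0, 0), u * spec$r_sip_gap, u * 2 * spec$r_sip_gap)
    units[[length(units) + 1L]] <-
      list(rel = rel, species = c(spec$cation, spec$water, spec$anion),
           role = c("sip_cation", "sip_water", "sip_anion"))
  }
  n_cat_used <- n_cat_used + spec$n_sip
  n_an_used <- n_an_used + spec$n_sip
  n_w_used <- spec$n_sip
  if (n_cat_used > spec$n_cations || n_an_used > spec$n_anions)
    stop("planted counts exceed available ions")
  for (i in seq_len(spec$n_cations - n_cat_used))
    units[[length(units) + 1L]] <- list(rel = matrix(0, 1, 3),
                                        species = spec$cation, role = "free")
  for (i in seq_len(spec$n_anions - n_an_used))
    units[[length(units) + 1L]] <- list(rel = matrix(0, 1, 3),
                                        species = spec$anion, role = "free")
  for (i in seq_len(spec$n_waters - n_w_used))
    units[[length(units) + 1L]] <- list(rel = matrix(0, 1, 3),
                                        species = spec$water, role = "free")
  ## place unit centres with rejection so that particles from different
  ## units stay farther apart than the classification window
  extent <- vapply(units, function(u) max(sqrt(rowSums(u$rel^2))), numeric(1))
  centers <- matrix(NA_real_, length(units), 3)
  attempts <- 0L
  for (i in seq_along(units)) {
    repeat {
      attempts <- attempts + 1L
      if (attempts > 1e6)
        stop("box too small to disperse ", length(units), " planted units")
      p <- stats::runif(3, 0, L)
      if (i == 1L) break
      d <- sweep(centers[seq_len(i - 1L), , drop = FALSE], 2, p)
      d <- d - L * round(d / L)
      need <- clear + extent[i] + extent[seq_len(i - 1L)]
      if (all(sqrt(rowSums(d^2)) >= need)) break
    }
    centers[i, ] <- p
  }
  pos <- do.call(rbind, lapply(seq_along(units), function(i)
    sweep(units[[i]]$rel, 2, centers[i, ], `+`)))
  species <- unlist(lapply(units, `[[`, "species"))
  role <- unlist(lapply(units, `[[`, "role"))

  if (spec$tetrahedral_anions) {
    tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) /
      sqrt(3) * 1.52
    ai <- which(species == spec$anion)
    extra <- do.call(rbind, lapply(ai, function(k)
      sweep(tet, 2, pos[k, ], `+`)))
    pos <- rbind(pos, extra)
    species <- c(species, rep(paste0(spec$anion, "O"), 4 * length(ai)))
    role <- c(role, rep("anion_oxygen", 4 * length(ai)))
  }
  cfg <- configuration(pos, species, L)
  truth <- list(
    counts = c(cip = spec$n_cip, sip = spec$n_sip),
    r_contact = spec$r_contact,
    r_pair_sip = 2 * spec$r_sip_gap,
    roles = role)
  list(config = cfg, truth = truth)
}

#' Dipole-field generation settings
#'
#' @param alpha_prime polarizability volume per water-like site, A^3.
#' @param include_anions include anion charges in the polarising field.
#' @param water_species label of the dipole-carrying species.
#' @return an object of class \code{dipole_spec}.
#' @export
dipole_spec <- function(alpha_prime = 1.0, include_anions = TRUE,
                        water_species = "W") {
  if (alpha_prime < 0) stop("'alpha_prime' must be >= 0")
  structure(list(alpha_prime = alpha_prime,
                 include_anions = include_anions,
                 water_species = water_species),
            class = "dipole_spec")
}

#' Attach field-aligned induced dipoles to water-like sites
#'
#' Single-pass linear response: each water-like site receives
#' mu = alpha' * E_perm, where E_perm is the minimum-image Coulomb
#' field (in e/A^2) of all permanent ion charges taken from the model.
#' No self-consistency between induced dipoles is attempted.
#'
#' @param config a \code{\link{configuration}} containing water-like
#'   sites.
#' @param spec a \code{\link{dipole_spec}}.
#' @param model a \code{\link{pm_model}} supplying the ion charges;
#'   species present in the configuration but absent from the model
#'   (and the water species itself) contribute no field.
#' @return the configuration with a dipole matrix (debye) attached;
#'   non-water rows are zero.
#' @export
gen_dipole_field <- function(config, spec, model) {
  stopifnot(inherits(config, "pm_config"), inherits(spec, "dipole_spec"),
            inherits(model, "pm_model"))
  wi <- which(config$species == spec$water_species)
  if (!length(wi))
    stop("configuration has no '", spec$water_species, "' sites")
  qmap <- model$charge
  src <- which(config$species %in% names(qmap) &
               config$species != spec$water_species)
  if (!spec$include_anions)
    src <- src[qmap[config$species[src]] > 0]
  dip <- matrix(0, nrow(config$positions), 3)
  if (length(src)) {
    qs <- unname(qmap[config$species[src]])
    W <- config$positions[wi, , drop = FALSE]
    S <- config$positions[src, , drop = FALSE]
    L <- config$box_length
    dx <- .min_image(outer(W[, 1], S[, 1], `-`), L)
    dy <- .min_image(outer(W[, 2], S[, 2], `-`), L)
    dz <- .min_image(outer(W[, 3], S[, 3], `-`), L)
    r3 <- (dx^2 + dy^2 + dz^2)^(3 / 2)
    ## E at the water, pointing away from positive sources: q * rvec/r^3
    Ex <- (dx / r3) %*% qs
    Ey <- (dy / r3) %*% qs
    Ez <- (dz / r3) %*% qs
    dip[wi, ] <- spec$alpha_prime * cbind(Ex, Ey, Ez) * .const$eA_to_D
  }
  configuration(config$positions, config$species, config$box_length,
                dipoles = dip)
}

#' Generate a synthetic osmotic-coefficient curve
#'
#' Evaluates the primitive-model prediction at the requested cation
#' diameter (via \code{\link{predict_curve}}) and optionally adds
#' i.i.d. Gaussian noise.  Stands in for experimental curves.
#'
#' @param model_template binary-salt \code{\link{pm_model}}.
#' @param d_plus_plus cation diameter in angstrom.
#' @param molalities increasing molalities, mol/kg.
#' @param noise_sigma standard deviation of the added noise.
#' @param seed integer seed (used only when noise_sigma > 0).
#' @param ... passed to \code{\link{predict_curve}}.
#' @return an \code{\link{osmotic_curve}} (failed molalities, if any,
#'   are carried through as NA with the same flag).
#' @export
gen_osmotic_curve <- function(model_template, d_plus_plus, molalities,
                              noise_sigma = 0, seed = 1L, ...) {
  curve <- predict_curve(model_template, d_plus_plus, molalities, ...)
  if (noise_sigma > 0) {
    set.seed(seed)
    curve$phi <- curve$phi + stats::rnorm(nrow(curve), 0, noise_sigma)
  }
  curve
}
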