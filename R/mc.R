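## R-side driver for the Metropolis Monte Carlo engine: configuration
## setup, the run wrapper, Ewald energy access and the virial-route
## osmotic coefficient with block-averaged error bars.

#' Monte Carlo run settings
#'
#' @param n_particles named integer vector: particles per species.
#' @param box_length cubic box edge in angstrom.
#' @param max_displacement maximum trial displacement per axis, angstrom.
#' @param n_equilibration,n_production numbers of single-particle moves.
#' @param seed integer RNG seed; identical settings and seed give an
#'   identical trajectory.
#' @param ewald_alpha Ewald splitting parameter in 1/angstrom (default
#'   5.6 / box_length, which balances real and reciprocal errors at the
#'   default cutoffs).
#' @param ewald_kmax largest reciprocal-vector index.
#' @param real_cutoff real-space cutoff, at most box_length/2.
#' @param n_blocks number of blocks for error estimation.
#' @param n_snapshots configurations to retain from production.
#' @param rdf_bin RDF bin width in angstrom.
#' @return an object of class \code{mc_config}.
#' @export
mc_config <- function(n_particles, box_length, max_displacement = 1.0,
                      n_equilibration = 2e5, n_production = 1e6,
                      seed = 1L, ewald_alpha = 5.6 / box_length,
                      ewald_kmax = 8L, real_cutoff = box_length / 2,
                      n_blocks = 20L, n_snapshots = 10L, rdf_bin = 0.05) {
  if (is.null(names(n_particles)))
    stop("'n_particles' must be named by species")
  if (real_cutoff > box_length / 2 + 1e-9)
    stop("'real_cutoff' must be <= box_length/2")
  if (n_blocks < 10L) stop("need >= 10 blocks for error bars")
  structure(list(n_particles = n_particles, box_length = box_length,
                 max_displacement = max_displacement,
                 n_equilibration = n_equilibration,
                 n_production = n_production, seed = as.integer(seed),
                 ewald_alpha = ewald_alpha, ewald_kmax = as.integer(ewald_kmax),
                 real_cutoff = real_cutoff, n_blocks = as.integer(n_blocks),
                 n_snapshots = as.integer(n_snapshots), rdf_bin = rdf_bin),
            class = "mc_config")
}

#' Box settings matching an ionic state
#'
#' Chooses the cubic box that realises the number densities of
#' \code{state} with \code{n_pairs} formula units, and returns an
#' \code{\link{mc_config}} for it.
#'
#' @param model a \code{\link{pm_model}}.
#' @param state a \code{\link{pm_state}} with at least one nonzero density.
#' @param n_pairs formula units to place (per-species counts are scaled
#'   from the state's density ratios).
#' @param ... further arguments to \code{\link{mc_config}}.
#' @return an \code{mc_config}.
#' @export
mc_config_for_state <- function(model, state, n_pairs = 64L, ...) {
  rho <- state$number_densities
  if (all(rho == 0)) stop("state has zero density; choose the box directly")
  base <- min(rho[rho > 0])
  counts <- round(rho / base * n_pairs)
  L <- (sum(counts) / sum(rho))^(1 / 3)
  mc_config(n_particles = counts[counts > 0], box_length = L, ...)
}

## Random sequential insertion honouring hard cores.
.place_random <- function(species_idx, dmat, L, rng, max_attempts = 1e6) {
  n <- length(species_idx)
  pos <- matrix(0, n, 3)
  attempts <- 0L
  placed <- 0L
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop("could not place ", n, " particles without overlap after ",
           max_attempts, " attempts; lower the density")
    p <- stats::runif(3, 0, L)
    ok <- TRUE
    if (placed > 0L) {
      d <- sweep(pos[seq_len(placed), , drop = FALSE], 2, p)
      d <- d - L * round(d / L)
      r <- sqrt(rowSums(d^2))
      dmin <- dmat[species_idx[seq_len(placed)], species_idx[placed + 1L]]
      ok <- all(r >= dmin)
    }
    if (ok) {
      placed <- placed + 1L
      pos[placed, ] <- p
    }
  }
  pos
}

#' Run canonical Monte Carlo for a primitive model
#'
#' Markov chain of single-particle displacements with Metropolis
#' acceptance min(1, exp(-beta dU)); hard-core overlaps are always
#' rejected.  Coulomb energies use plain Ewald summation with tin-foil
#' boundary conditions.  The run is bit-reproducible for a given
#' \code{mc_config} on one platform.
#'
#' @param model a \code{\link{pm_model}}.
#' @param config an \code{\link{mc_config}}; its particle counts must be
#'   electroneutral under the model charges.
#' @return an object of class \code{mc_result}: acceptance rate, mean
#'   beta-energy per particle with block standard error, per-pair RDF
#'   accumulators (overall and per block), retained snapshots as
#'   \code{\link{configuration}} objects, and the maximum relative drift
#'   between the running energy and periodic full recomputations.
#' @export
run_mc <- function(model, config) {
  stopifnot(inherits(model, "pm_model"), inherits(config, "mc_config"))
  nm <- names(model$charge)
  counts <- config$n_particles[nm]
  counts[is.na(counts)] <- 0L
  names(counts) <- nm
  qtot <- sum(model$charge * counts)
  if (abs(qtot) > 1e-9)
    stop("particle counts are not electroneutral (total charge ", qtot, ")")
  if (config$box_length <= 2 * max(model$closest_approach))
    stop("box_length must exceed twice the largest closest approach")
  species_idx <- rep(seq_along(nm), counts)          # 1-based
  N <- length(species_idx)
  set.seed(config$seed)
  pos <- .place_random(species_idx, model$closest_approach,
                       config$box_length, max_attempts = 1e6)
  qvec <- unname(model$charge)[species_idx]
  raw <- .cpp_run_mc(pos, qvec, species_idx - 1L, model$closest_approach,
                     config$box_length, bjerrum_length(model),
                     config$ewald_alpha, config$ewald_kmax,
                     config$real_cutoff, config$max_displacement,
                     config$n_equilibration, config$n_production,
                     config$seed, config$rdf_bin,
                     config$real_cutoff, config$n_blocks,
                     config$n_snapshots, 1e4L)

  nb <- raw$n_bins
  npair <- raw$n_pair_channels
  B <- config$n_blocks
  cnt <- array(raw$rdf_counts, dim = c(nb, npair, B))
  edges <- seq(0, nb * config$rdf_bin, by = config$rdf_bin)
  be <- raw$block_energy / N
  snaps <- lapply(raw$snapshots[seq_len(raw$n_snapshots_taken)],
                  function(p) configuration(p, nm[species_idx],
                                            config$box_length))
  structure(list(model = model, config = config,
                 species = nm, counts = counts,
                 acceptance_rate = raw$acceptance_rate,
                 energy_per_particle = mean(be),
                 energy_se = stats::sd(be) / sqrt(B),
                 block_energy = be,
                 rdf_bin_edges = edges,
                 rdf_block_counts = cnt,
                 rdf_samples = raw$rdf_samples,
                 snapshots = snaps,
                 max_energy_drift = raw$max_energy_drift,
                 n_particles = N),
            class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf("MC run: %d particles, %.3g production moves\n",
              x$n_particles, x$config$n_production))
  cat(sprintf("  acceptance rate      : %.3f\n", x$acceptance_rate))
  cat(sprintf("  beta-energy/particle : %.5f +/- %.5f\n",
              x$energy_per_particle, x$energy_se))
  cat(sprintf("  max energy drift     : %.2e (relative)\n",
              x$max_energy_drift))
  invisible(x)
}

## Contact value of a sampled (noisy) histogram g(r): counts-weighted
## linear fit of log g over the first bins outside the core,
## extrapolated to r = d.  Log space linearises the steep
## Boltzmann-like rise at contact, and pooling several bins suppresses
## the counting noise a 3-point polynomial would amplify.
.mc_contact_value <- function(mids, g, counts, d, window = 0.25) {
  k <- which(mids >= d & mids <= d + window & g > 0)
  if (length(k) < 3) k <- utils::head(which(mids >= d & g > 0), 3)
  if (length(k) < 2) return(NA_real_)
  fit <- stats::lm.wfit(cbind(1, mids[k] - d), log(g[k]), w = counts[k])
  exp(fit$coefficients[[1]])
}

## g_ij(r) from raw pair counts for one species pair over chosen blocks.
.mc_rdf_pair <- function(result, i, j, blocks = NULL) {
  ns <- length(result$species)
  if (is.null(blocks)) blocks <- seq_len(dim(result$rdf_block_counts)[3])
  a <- min(i, j); b <- max(i, j)
  p <- (a - 1) * ns - (a - 1) * (a - 2) / 2 + (b - a) + 1
  cnt <- rowSums(result$rdf_block_counts[, p, blocks, drop = FALSE])
  nsamp <- sum(result$rdf_samples[blocks])
  V <- result$config$box_length^3
  edges <- result$rdf_bin_edges
  vshell <- 4 / 3 * pi * diff(edges^3)
  ni <- result$counts[i]; nj <- result$counts[j]
  npairs_ideal <- if (i == j) ni * (ni - 1) / 2 else ni * nj
  expected <- npairs_ideal * vshell / V * nsamp
  g <- ifelse(expected > 0, cnt / expected, 0)
  list(g = g, counts = cnt, edges = edges)
}

#' Extract an RDF from a Monte Carlo run
#'
#' @param result an \code{\link{run_mc}} result.
#' @param species_A,species_B species names.
#' @return an \code{rdf_result} (see \code{\link{compute_rdf}}).
#' @export
mc_rdf <- function(result, species_A, species_B) {
  stopifnot(inherits(result, "mc_result"))
  i <- match(species_A, result$species)
  j <- match(species_B, result$species)
  if (is.na(i) || is.na(j)) stop("unknown species")
  pr <- .mc_rdf_pair(result, i, j)
  rdf_result(pr$edges, pr$g, pr$counts,
             rho_B = result$counts[j] / result$config$box_length^3)
}

#' Osmotic coefficient from a Monte Carlo run
#'
#' Virial route, as in \code{\link{osmotic_coefficient}}: hard-core
#' contact term from quadratic extrapolation of the sampled g_ij(r) to
#' each contact distance, plus beta<E_el>/(3N).  The estimate and its
#' standard error come from recomputing phi on each block.
#'
#' @param result an \code{mc_result} from \code{\link{run_mc}}.
#' @return list with \code{phi}, \code{se}, and the per-block values.
#' @export
mc_osmotic_coefficient <- function(result) {
  stopifnot(inherits(result, "mc_result"))
  model <- result$model
  ns <- length(result$species)
  V <- result$config$box_length^3
  rho <- result$counts / V
  rho_tot <- sum(rho)
  B <- dim(result$rdf_block_counts)[3]
  mids <- (result$rdf_bin_edges[-1] + utils::head(result$rdf_bin_edges, -1)) / 2

  phi_block <- vapply(seq_len(B), function(b) {
    contact <- 0
    for (i in seq_len(ns)) for (j in seq_len(ns)) {
      dij <- model$closest_approach[i, j]
      pr <- .mc_rdf_pair(result, i, j, blocks = b)
      k <- which(mids >= dij)
      if (length(k) < 3) stop("no contact-region bins populated for pair ",
                              result$species[i], "-", result$species[j])
      gc <- .mc_contact_value(mids, pr$g, pr$counts, dij)
      contact <- contact + rho[i] * rho[j] * dij^3 * gc
    }
    1 + 2 * pi / (3 * rho_tot) * contact + result$block_energy[b] / 3
  }, numeric(1))
  list(phi = mean(phi_block), se = stats::sd(phi_block) / sqrt(B),
       blocks = phi_block)
}

#' Ewald Coulomb energy of a configuration
#'
#' Real-space, reciprocal-space and self terms of the plain Ewald sum
#' for a cubic periodic box with tin-foil boundary conditions, in units
#' of k_B T.  For an electroneutral configuration the value is
#' independent of the splitting parameter (given converged cutoffs).
#'
#' @param config a \code{\link{configuration}}.
#' @param model a \code{\link{pm_model}} supplying charges and the
#'   Bjerrum length.
#' @param alpha splitting parameter in 1/angstrom.
#' @param kmax largest reciprocal-vector index.
#' @param real_cutoff real-space cutoff in angstrom.
#' @return total Coulomb energy in k_B T.
#' @export
ewald_energy <- function(config, model, alpha = 5.6 / config$box_length,
                         kmax = 8L, real_cutoff = config$box_length / 2) {
  stopifnot(inherits(config, "pm_config"), inherits(model, "pm_model"))
  k <- .species_index(model, config$species)
  q <- unname(model$charge)[k]
  if (abs(sum(q)) > 1e-9)
    stop("configuration is not electroneutral; tin-foil Ewald requires it")
  if (real_cutoff > config$box_length / 2 + 1e-9)
    stop("'real_cutoff' must be <= box_length/2")
  .cpp_ewald_energy(config$positions, q, config$box_length,
                    bjerrum_length(model), alpha, as.integer(kmax),
                    real_cutoff)
}

#' Metropolis acceptance probability
#'
#' min(1, exp(-delta)), the acceptance rule shared by single-particle
#' displacements and replica-exchange swaps, as a function of the
#' beta-energy change.
#'
#' @param delta_beta_U beta-energy difference (dimensionless).
#' @return acceptance probability in (0, 1].
#' @export
exchange_acceptance <- function(delta_beta_U) {
  if (any(is.na(delta_beta_U)))
    stop("'delta_beta_U' must be finite or +/-Inf")
  pmin(1, exp(-delta_beta_U))
}
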