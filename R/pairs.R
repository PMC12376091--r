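## Distance-window classification of ion pairs (contact vs
## solvent-shared) and solvation-shell membership.

#' Classify cation-anion pairs as CIP, SIP or unpaired
#'
#' Pure radial classification: a cation-anion pair at minimum-image
#' distance r is a contact ion pair (CIP) when r < r_cip, a
#' solvent-shared ion pair (SIP) when r_cip <= r < r_sip, and unpaired
#' otherwise.  An anion may simultaneously pair with several cations
#' (triple ions and larger aggregates), so CIP counts per cation can
#' exceed one.
#'
#' @param config a \code{\link{configuration}}.
#' @param cation,anion species labels.
#' @param r_cip,r_sip classification windows in angstrom, 0 < r_cip <
#'   r_sip.
#' @return list with \code{counts} (named: cip, sip, unpaired) and
#'   \code{pairs}, a data frame of every cation-anion pair with its
#'   distance and label.
#' @export
classify_pairs <- function(config, cation, anion, r_cip, r_sip) {
  stopifnot(inherits(config, "pm_config"))
  if (!(r_cip > 0 && r_cip < r_sip))
    stop("need 0 < r_cip < r_sip (got ", r_cip, ", ", r_sip, ")")
  ci <- which(config$species == cation)
  ai <- which(config$species == anion)
  if (!length(ci) || !length(ai)) {
    empty <- data.frame(cation = integer(0), anion = integer(0),
                        r = numeric(0), label = character(0))
    return(list(counts = c(cip = 0L, sip = 0L, unpaired = 0L), pairs = empty))
  }
  r <- .pair_distances(config$positions[ci, , drop = FALSE],
                       config$positions[ai, , drop = FALSE],
                       config$box_length)
  lab <- ifelse(r < r_cip, "CIP", ifelse(r < r_sip, "SIP", "unpaired"))
  df <- data.frame(cation = rep(ci, times = length(ai)),
                   anion = rep(ai, each = length(ci)),
                   r = as.vector(r), label = as.vector(lab))
  counts <- c(cip = sum(df$label == "CIP"),
              sip = sum(df$label == "SIP"),
              unpaired = sum(df$label == "unpaired"))
  list(counts = counts, pairs = df)
}

#' First-solvation-shell membership
#'
#' A partner particle (e.g. a water oxygen) is in-shell when its
#' minimum-image distance to any centre particle (e.g. a cation) is
#' below the cutoff.  Membership is counted once per partner regardless
#' of how many centres it is close to.  The default cutoff of 3.2 A is
#' the metal-water oxygen shell boundary for small divalent cations.
#'
#' @param config a \code{\link{configuration}}.
#' @param center_species,partner_species species labels.
#' @param cutoff shell cutoff in angstrom (> 0).
#' @return logical vector over partner particles (in partner order);
#'   empty when no partners exist, all-FALSE when no centres exist.
#' @export
shell_membership <- function(config, center_species, partner_species,
                             cutoff = 3.2) {
  stopifnot(inherits(config, "pm_config"))
  if (cutoff <= 0) stop("'cutoff' must be > 0")
  pi_ <- which(config$species == partner_species)
  ci <- which(config$species == center_species)
  if (!length(pi_)) return(logical(0))
  if (!length(ci)) return(rep(FALSE, length(pi_)))
  r <- .pair_distances(config$positions[pi_, , drop = FALSE],
                       config$positions[ci, , drop = FALSE],
                       config$box_length)
  apply(r < cutoff, 1, any)
}

#' Excess induced dipole of shell waters
#'
#' Mean induced-dipole magnitude of first-shell partner particles minus
#' the mean over out-of-shell partners, averaged over frames.  Frames in
#' which either class is empty are skipped (with a message).  The
#' out-of-shell average runs over all partners outside every centre
#' shell, including those near other species.
#'
#' @param configurations a \code{\link{configuration}} with dipoles, or
#'   a list of them.
#' @param center_species the ion species defining the shells.
#' @param partner_species the dipole-carrying (water-like) species.
#' @param cutoff shell cutoff in angstrom (default 3.2).
#' @return excess induced dipole in debye.
#' @export
delta_mu_ind <- function(configurations, center_species,
                         partner_species, cutoff = 3.2) {
  if (inherits(configurations, "pm_config"))
    configurations <- list(configurations)
  vals <- numeric(0)
  skipped <- 0L
  for (fr in configurations) {
    if (is.null(fr$dipoles))
      stop("configuration carries no induced dipoles")
    inshell <- shell_membership(fr, center_species, partner_species, cutoff)
    pi_ <- which(fr$species == partner_species)
    mu <- sqrt(rowSums(fr$dipoles[pi_, , drop = FALSE]^2))
    if (!any(inshell) || all(inshell)) { skipped <- skipped + 1L; next }
    vals <- c(vals, mean(mu[inshell]) - mean(mu[!inshell]))
  }
  if (skipped > 0)
    message(skipped, " frame(s) skipped: empty shell or empty bulk class")
  if (!length(vals)) stop("no frame had both shell and bulk waters")
  mean(vals)
}
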