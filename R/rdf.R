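## Radial distribution functions from configurations, peak/minimum
## detection and coordination-number integrals.

#' Radial distribution function container
#'
#' @param bin_edges vector of bin edges in angstrom (half-open bins
#'   [lo, hi)).
#' @param g g(r) per bin.
#' @param counts raw pair counts per bin.
#' @param rho_B number density of the partner species used for
#'   normalisation, per cubic angstrom.
#' @return an object of class \code{rdf_result}.
#' @export
rdf_result <- function(bin_edges, g, counts, rho_B) {
  nb <- length(bin_edges) - 1L
  if (length(g) != nb || length(counts) != nb)
    stop("'g' and 'counts' must have one value per bin")
  if (any(g < 0)) stop("g(r) cannot be negative")
  structure(list(bin_edges = as.numeric(bin_edges), g = as.numeric(g),
                 counts = as.numeric(counts), rho_B = rho_B),
            class = "rdf_result")
}

#' @export
print.rdf_result <- function(x, ...) {
  cat(sprintf("RDF: %d bins on [0, %.4g] A, %.0f pairs counted, rho_B = %.4g A^-3\n",
              length(x$g), max(x$bin_edges), sum(x$counts), x$rho_B))
  invisible(x)
}

#' @export
plot.rdf_result <- function(x, ...) {
  mids <- (x$bin_edges[-1] + utils::head(x$bin_edges, -1)) / 2
  graphics::plot(mids, x$g, type = "l", xlab = "r (A)", ylab = "g(r)", ...)
  graphics::abline(h = 1, lty = 3)
  invisible(x)
}

.bin_mids <- function(rdf) (rdf$bin_edges[-1] + utils::head(rdf$bin_edges, -1)) / 2

#' Radial distribution function between two species
#'
#' Histograms minimum-image distances over one or more frames and
#' normalises by the ideal-gas shell count, so that g -> 1 for
#' uncorrelated particles.  For A = B, self pairs are excluded and each
#' pair is counted once.
#'
#' @param configurations a \code{\link{configuration}} or list of them
#'   (all with the same box length and composition).
#' @param species_A,species_B species labels.
#' @param bin_width bin width in angstrom.
#' @param r_max histogram range; must not exceed box_length/2.
#' @return an \code{\link{rdf_result}}.
#' @export
compute_rdf <- function(configurations, species_A, species_B,
                        bin_width = 0.05, r_max = NULL) {
  if (inherits(configurations, "pm_config"))
    configurations <- list(configurations)
  if (!length(configurations)) stop("need at least one configuration")
  L <- configurations[[1]]$box_length
  if (is.null(r_max)) r_max <- L / 2
  if (r_max > L / 2 + 1e-9)
    stop("'r_max' must not exceed half the box length")
  edges <- seq(0, r_max, by = bin_width)
  if (max(edges) < r_max) edges <- c(edges, max(edges) + bin_width)
  nb <- length(edges) - 1L
  counts <- numeric(nb)
  nA <- nB <- 0
  same <- identical(species_A, species_B)
  for (fr in configurations) {
    A <- fr$positions[fr$species == species_A, , drop = FALSE]
    B <- fr$positions[fr$species == species_B, , drop = FALSE]
    nA <- nrow(A); nB <- nrow(B)
    if (nA == 0 || nB == 0) next
    r <- .pair_distances(A, B, fr$box_length)
    r <- if (same) r[upper.tri(r)] else as.vector(r)
    r <- r[r < r_max]
    ## half-open [lo, hi) binning
    counts <- counts + tabulate(pmin(floor(r / bin_width) + 1L, nb), nb)
  }
  nframes <- length(configurations)
  V <- L^3
  vshell <- 4 / 3 * pi * diff(edges^3)
  npairs_ideal <- if (same) nA * (nA - 1) / 2 else nA * nB
  expected <- npairs_ideal * vshell / V * nframes
  g <- ifelse(expected > 0, counts / expected, 0)
  rdf_result(edges, g, counts, rho_B = nB / V)
}

## 5-point moving average used before extremum detection; endpoints
## shrink the window symmetrically.
.smooth5 <- function(y) {
  n <- length(y)
  out <- y
  for (i in seq_len(n)) {
    w <- max(1, i - 2):min(n, i + 2)
    out[i] <- mean(y[w])
  }
  out
}

## 3-point parabolic refinement of an extremum at index k on (x, y).
.parabolic_vertex <- function(x, y, k) {
  if (k <= 1 || k >= length(x)) return(x[k])
  denom <- y[k - 1] - 2 * y[k] + y[k + 1]
  if (abs(denom) < .Machine$double.eps) return(x[k])
  h <- (x[k + 1] - x[k - 1]) / 2
  x[k] + h * (y[k - 1] - y[k + 1]) / (2 * denom)
}

## indices of interior local maxima of y (strictly above both plateau
## neighbours after smoothing)
.local_maxima <- function(y) {
  n <- length(y)
  if (n < 3) return(integer(0))
  which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
}

#' Position of the first RDF peak
#'
#' First local maximum of g(r) exceeding 1, located on a 5-point
#' smoothed curve and refined by 3-point parabolic interpolation on the
#' raw curve.
#'
#' @param rdf an \code{\link{rdf_result}}.
#' @return peak position in angstrom, or \code{NA} if no local maximum
#'   above 1 exists.
#' @export
find_first_peak <- function(rdf) {
  stopifnot(inherits(rdf, "rdf_result"))
  if (sum(rdf$g > 0) < 5) stop("need at least 5 bins with g > 0")
  mids <- .bin_mids(rdf)
  gs <- .smooth5(rdf$g)
  cand <- .local_maxima(gs)
  cand <- cand[gs[cand] > 1]
  if (!length(cand)) return(NA_real_)
  k <- cand[1]
  ## refine on the raw curve near the smoothed maximum
  w <- max(2, k - 2):min(length(mids) - 1, k + 2)
  k_raw <- w[which.max(rdf$g[w])]
  .parabolic_vertex(mids, rdf$g, k_raw)
}

#' Minimum separating the CIP and SIP peaks
#'
#' Lowest interior minimum of g(r) between the first two local maxima
#' (contact and solvent-shared peaks), detected on a 5-point smoothed
#' curve and refined parabolically on the raw curve.
#'
#' @param rdf an \code{\link{rdf_result}}.
#' @return minimum position in angstrom, or \code{NA} when fewer than
#'   two peaks exist.
#' @export
find_cip_sip_minimum <- function(rdf) {
  stopifnot(inherits(rdf, "rdf_result"))
  mids <- .bin_mids(rdf)
  gs <- .smooth5(rdf$g)
  peaks <- .local_maxima(gs)
  peaks <- peaks[gs[peaks] > 1]
  if (length(peaks) < 2) return(NA_real_)
  p1 <- peaks[1]; p2 <- peaks[2]
  if (p2 - p1 < 2) return(NA_real_)
  seg <- (p1 + 1):(p2 - 1)
  k <- seg[which.min(gs[seg])]
  w <- max(2, k - 2):min(length(mids) - 1, k + 2)
  k_raw <- w[which.min(rdf$g[w])]
  .parabolic_vertex(mids, rdf$g, k_raw)
}

#' Coordination number up to a cutoff
#'
#' N(r_cut) = 4 pi rho_B int_0^{r_cut} g(r) r^2 dr, by the trapezoid
#' rule on bin centres (with the r = 0 origin included).
#'
#' @param rdf an \code{\link{rdf_result}}.
#' @param r_cut integration limit in angstrom, within the histogram
#'   range.
#' @return dimensionless coordination number.
#' @export
coordination_number <- function(rdf, r_cut) {
  stopifnot(inherits(rdf, "rdf_result"))
  mids <- .bin_mids(rdf)
  if (r_cut > max(rdf$bin_edges) + 1e-9)
    stop("'r_cut' lies beyond the histogram range")
  x <- c(0, mids[mids <= r_cut])
  y <- c(0, rdf$g[mids <= r_cut] * mids[mids <= r_cut]^2)
  ## close the interval exactly at r_cut by linear interpolation
  if (max(x) < r_cut && any(mids > r_cut)) {
    k <- which(mids > r_cut)[1]
    gcut <- stats::approx(mids, rdf$g, xout = r_cut, rule = 2)$y
    x <- c(x, r_cut); y <- c(y, gcut * r_cut^2)
  }
  integral <- sum(diff(x) * (utils::head(y, -1) + y[-1]) / 2)
  4 * pi * rdf$rho_B * integral
}

#' Ion-pairing summary of a cation-anion RDF
#'
#' Bundles the first-peak position, the CIP/SIP separating minimum and
#' the contact population N_contact (coordination number integrated to
#' that minimum).  When no second peak exists, N_contact integrates to
#' the first minimum after the first peak instead and the result is
#' flagged.
#'
#' @param rdf cation-anion \code{\link{rdf_result}}.
#' @return list with \code{n_contact}, \code{r_first_peak},
#'   \code{r_cip_sip_min}, \code{fallback_cutoff} (TRUE when the
#'   CIP/SIP minimum was unavailable).
#' @export
pairing_summary <- function(rdf) {
  r_peak <- find_first_peak(rdf)
  r_min <- find_cip_sip_minimum(rdf)
  fallback <- FALSE
  if (is.na(r_min) && !is.na(r_peak)) {
    ## first local minimum after the first peak
    mids <- .bin_mids(rdf)
    gs <- .smooth5(rdf$g)
    k0 <- which.min(abs(mids - r_peak))
    n <- length(gs)
    mins <- which(gs[2:(n - 1)] < gs[1:(n - 2)] & gs[2:(n - 1)] <= gs[3:n]) + 1L
    mins <- mins[mins > k0]
    if (length(mins)) {
      r_min <- .parabolic_vertex(mids, rdf$g, mins[1])
      fallback <- TRUE
    }
  }
  n_contact <- if (is.na(r_min)) NA_real_ else coordination_number(rdf, r_min)
  list(n_contact = n_contact, r_first_peak = r_peak,
       r_cip_sip_min = r_min, fallback_cutoff = fallback)
}
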