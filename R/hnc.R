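## Multicomponent Ornstein-Zernike solver with the hypernetted-chain
## closure for primitive-model electrolytes, and the virial-route
## osmotic coefficient computed from the converged pair structure.
##
## Long-range handling: the Coulomb tail -beta*u is split with an
## erf/erfc pair at splitting parameter kappa_s (Ng renormalisation), so
## every Fourier transform acts on an absolutely integrable function.
## The iteration variable is gamma* = h - c - beta*u_long, which is
## short-ranged even for charged systems.

#' Radial grid for the integral-equation solver
#'
#' @param n_points number of radial nodes (a power of two, >= 2^12).
#' @param dr grid spacing in angstrom (<= 0.05).
#' @return an object of class \code{pm_grid}; node k sits at r = k*dr.
#' @export
radial_grid <- function(n_points = 2^14, dr = 0.02) {
  if (n_points < 2^12 || bitwAnd(n_points, n_points - 1L) != 0)
    stop("'n_points' must be a power of two >= 4096")
  if (dr <= 0 || dr > 0.05) stop("'dr' must be in (0, 0.05] angstrom")
  structure(list(n_points = as.integer(n_points), dr = dr,
                 r = seq_len(n_points) * dr),
            class = "pm_grid")
}

## DST-I of x (length m): S_n = sum_j x_j sin(pi j n / (m+1)).
## m is chosen as n_points - 1 so the embedded FFT length 2*(m+1) is a
## power of two.
.dst1 <- function(x) {
  m <- length(x)
  y <- c(0, x, 0, -rev(x))
  -Im(stats::fft(y))[2:(m + 1)] / 2
}

## Column-wise DST-I of a matrix (one FFT call for all pair channels).
.dst1m <- function(X) {
  m <- nrow(X)
  Y <- rbind(0, X, 0, -X[m:1, , drop = FALSE])
  -Im(stats::mvfft(Y))[2:(m + 1), , drop = FALSE] / 2
}

## Forward 3D Fourier transform of a radial function sampled on j*dr,
## j = 1..m:  fhat(k_n) = (4 pi dr / k_n) * DST(r f)_n,  k_n = pi n/((m+1) dr).
.fbt_fwd <- function(f, r, k, dr) 4 * pi * dr / k * .dst1(r * f)
.fbt_inv <- function(fhat, r, k, dk) dk / (2 * pi^2 * r) * .dst1(k * fhat)

## Pack symmetric pair functions as a matrix [r-node, pair], pairs in
## upper-triangle order.
.pair_index <- function(ns) {
  idx <- which(upper.tri(matrix(0, ns, ns), diag = TRUE), arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

## Solve H = (I - C P)^{-1} C at every k for the packed C.
## Vectorised closed forms for 1 and 2 species; general small-matrix
## loop otherwise.
.oz_solve <- function(chat, rho, pidx) {
  ns <- length(rho)
  if (ns == 1L) {
    c11 <- chat[, 1]
    return(cbind(c11 / (1 - rho[1] * c11)))
  }
  if (ns == 2L) {
    c11 <- chat[, 1]; c12 <- chat[, 2]; c22 <- chat[, 3]
    d11 <- 1 - rho[1] * c11; d12 <- -rho[2] * c12
    d21 <- -rho[1] * c12;    d22 <- 1 - rho[2] * c22
    det <- d11 * d22 - d12 * d21
    h11 <- (d22 * c11 - d12 * c12) / det
    h12 <- (d22 * c12 - d12 * c22) / det
    h22 <- (-d21 * c12 + d11 * c22) / det
    return(cbind(h11, h12, h22, deparse.level = 0))
  }
  nk <- nrow(chat)
  out <- matrix(0, nk, nrow(pidx))
  C <- matrix(0, ns, ns)
  for (kk in seq_len(nk)) {
    C[pidx] <- chat[kk, ]
    C[pidx[, c(2, 1), drop = FALSE]] <- chat[kk, ]
    H <- solve(diag(ns) - C %*% diag(rho, ns), C)
    out[kk, ] <- H[pidx]
  }
  out
}

#' Solve the Ornstein-Zernike equation with the HNC closure
#'
#' Picard iteration with adaptive mixing on the renormalised indirect
#' correlation function.  Strongly coupled states are reached by
#' coupling continuation: the ion charges are scaled up stepwise at the
#' target density, each step warm-started from the previous solution.
#' Non-convergence (including the known absence of HNC solutions for
#' dilute, strongly associating 2:2 electrolytes) raises a typed
#' condition carrying the last residual.
#'
#' @param model a \code{\link{pm_model}}.
#' @param state an electroneutral \code{\link{pm_state}}.
#' @param grid a \code{\link{radial_grid}}.
#' @param tolerance convergence threshold on the max-norm of the update
#'   of the short-range direct correlation function.
#' @param max_iter maximum Picard iterations per density step.
#' @param kappa_s erf/erfc splitting parameter in 1/angstrom.
#' @param init optional previous \code{pm_corr} solution used as the
#'   starting point (continuation); skips the coupling ramp.
#' @return an object of class \code{pm_corr}: the grid, arrays
#'   \code{h}, \code{c}, \code{g} indexed \code{[r, i, j]}, the state,
#'   a \code{converged} flag and the final \code{residual}.
#' @export
solve_hnc <- function(model, state, grid = radial_grid(),
                      tolerance = 1e-8, max_iter = 3000L, kappa_s = 1.0,
                      init = NULL) {
  stopifnot(inherits(model, "pm_model"), inherits(state, "pm_state"),
            inherits(grid, "pm_grid"))
  rho_target <- state$number_densities
  lB <- bjerrum_length(model)
  kap2 <- 4 * pi * lB * sum(model$charge^2 * rho_target)
  if (kap2 > 0) {
    debye <- 1 / sqrt(kap2)
    if (grid$n_points * grid$dr < 40 * debye)
      warning(sprintf(
        "grid extent %.0f A is below 40 Debye lengths (%.0f A); tails may be truncated",
        grid$n_points * grid$dr, 40 * debye))
  }

  gs <- if (!is.null(init)) attr(init, "gamma_star") else NULL
  ## Adaptive coupling continuation: attempt the full-coupling solve
  ## first; on failure, solve a charge-scaled model at the same density
  ## and bisect the scale step until the target is reached.  (Ramping
  ## density instead walks into the dilute strong-coupling region where
  ## the HNC iteration is unstable for associating 2:2 electrolytes.)
  scales <- 1
  res <- NULL
  s_prev <- 0
  warm <- !is.null(gs)
  while (length(scales)) {
    s <- scales[1]
    tol_s <- if (s < 1) max(tolerance, 1e-5) else tolerance
    mdl_s <- if (s == 1) model else scale_charges(model, s)
    res <- .hnc_iterate(mdl_s, rho_target, grid,
                        tol_s, max_iter, kappa_s, gamma_star = gs)
    if (!res$converged) {
      if (warm) {
        ## a failed warm start is abandoned entirely: restart cold
        ## rather than bisecting from a foreign starting point
        return(solve_hnc(model, state, grid, tolerance = tolerance,
                         max_iter = max_iter, kappa_s = kappa_s,
                         init = NULL))
      }
      ## halve the continuation step before giving up
      if (s - s_prev > 0.02 && any(model$charge != 0)) {
        scales <- c((s_prev + s) / 2, scales)
        next
      }
      stop(structure(class = c("hnc_nonconvergence", "error", "condition"),
                     list(message = sprintf(
                            "HNC failed to converge (residual %.3g at charge scale %.3g)",
                            res$residual, s),
                          call = sys.call(-1), residual = res$residual)))
    }
    gs <- res$gamma_star
    warm <- FALSE
    s_prev <- s
    scales <- scales[-1]
  }
  out <- structure(list(grid = grid, h = res$h, c = res$c, g = res$g,
                        state = state, converged = TRUE,
                        residual = res$residual, iterations = res$iterations,
                        model = model),
                   class = "pm_corr")
  attr(out, "gamma_star") <- res$gamma_star
  ## HNC has spurious solution branches for associating electrolytes;
  ## they violate local electroneutrality grossly.  A warm start that
  ## converged onto one is discarded and re-solved by cold continuation.
  if (!is.null(init) && any(model$charge != 0) && sum(rho_target) > 0) {
    sc <- screening_charge(out)
    if (max(abs(sc + model$charge)) > 0.05 * max(abs(model$charge)))
      return(solve_hnc(model, state, grid, tolerance = tolerance,
                       max_iter = max_iter, kappa_s = kappa_s, init = NULL))
  }
  out
}

## One fixed-density HNC solve.  gamma_star: matrix [m, npair] or NULL.
.hnc_iterate <- function(model, rho, grid, tol, max_iter, kappa_s,
                         gamma_star = NULL) {
  ns <- length(rho)
  N <- grid$n_points
  m <- N - 1L                       # transform length; node N pinned to asymptote
  dr <- grid$dr
  r <- grid$r[seq_len(m)]
  dk <- pi / (N * dr)
  k <- seq_len(m) * dk
  pidx <- .pair_index(ns)
  npair <- nrow(pidx)
  z <- unname(model$charge)
  lB <- bjerrum_length(model)

  zz <- z[pidx[, 1]] * z[pidx[, 2]]
  dij <- model$closest_approach[pidx]
  core <- outer(r, dij, `<`)                       # [m, npair]
  bus <- outer(lB * .erfc(kappa_s * r) / r, zz)     # short-range beta*u
  bul <- outer(lB * .erf(kappa_s * r) / r, zz)      # long-range beta*u
  bul_hat <- outer(4 * pi * lB * exp(-k^2 / (4 * kappa_s^2)) / k^2, zz)
  ## Analytic carrier for the slowly decaying Debye tail of gamma* =
  ## h - c*: the difference of two screened Coulombs (kappa from the
  ## ionic strength, kappa2 fixed) is cusp-free at r = 0, finite at
  ## k = 0 for any density including zero, and exactly transformable,
  ## so the tail picks up no grid periodization or truncation error.
  kap <- sqrt(4 * pi * lB * sum(z^2 * rho))
  kap2c <- 2 * kappa_s
  if (abs(kap - kap2c) < 1e-6) kap2c <- kap2c + 1e-3
  busc_hat <- outer(4 * pi * lB * (1 / (k^2 + kap^2) -
                                   1 / (k^2 + kap2c^2)), zz)
  busc <- outer(lB * (exp(-kap * r) - exp(-kap2c * r)) / r, zz)

  if (is.null(gamma_star)) gamma_star <- matrix(0, m, npair)
  mix <- 0.1
  res_prev <- Inf
  residual <- Inf
  stag_best <- Inf                   # best residual at the last stagnation check
  it <- 0L
  g <- cs <- matrix(0, m, npair)
  for (it in seq_len(max_iter)) {
    expo <- -bus + gamma_star
    expo[expo > 300] <- 300                        # overflow guard, transient only
    g <- exp(expo)
    g[core] <- 0
    cs_new <- g - 1 - gamma_star                   # c* = c + beta*u_long
    if (it > 1L) {
      residual <- max(abs(cs_new - cs))
      if (residual < tol) { cs <- cs_new; break }
    }
    cs <- cs_new
    cs_hat <- (4 * pi * dr / k) * .dst1m(r * cs)
    c_hat <- cs_hat - bul_hat
    h_hat <- .oz_solve(c_hat, rho, pidx)
    ## gamma*-hat = H - C*; its slowly decaying Coulomb part is routed
    ## around the discrete transform via the screened analytic pair, so
    ## the tail carries no grid periodization error (and the
    ## zero-density limit g = exp(-beta u) is exact)
    g_hat <- h_hat - cs_hat + busc_hat
    gsn <- (dk / (2 * pi^2 * r)) * .dst1m(k * g_hat) - busc
    step <- gsn - gamma_star
    stepn <- max(abs(step))
    if (!is.finite(stepn) || stepn > 1e6) break   # diverged: abort early
    ## stagnation abort: near the HNC no-solution boundary the residual
    ## oscillates without progress; converging runs halve it every
    ## hundred iterations or so
    if (it %% 400L == 0L) {
      if (residual > tol && residual > stag_best / 2) break
      stag_best <- residual
    }
    mix <- if (stepn < res_prev) min(mix * 1.1, 0.8) else max(mix * 0.5, 0.02)
    res_prev <- stepn
    gamma_star <- gamma_star + mix * step
  }
  conv <- residual < tol
  ## unpack to [r, i, j] arrays on the full grid (node N at asymptote)
  h <- array(0, c(N, ns, ns)); cf <- array(0, c(N, ns, ns))
  garr <- array(1, c(N, ns, ns))
  cfull <- cs - bul
  hfull <- g - 1
  for (p in seq_len(npair)) {
    i <- pidx[p, 1]; j <- pidx[p, 2]
    h[seq_len(m), i, j] <- h[seq_len(m), j, i] <- hfull[, p]
    cf[seq_len(m), i, j] <- cf[seq_len(m), j, i] <- cfull[, p]
    garr[seq_len(m), i, j] <- garr[seq_len(m), j, i] <- g[, p]
  }
  nm <- names(model$charge)
  dimnames(h) <- dimnames(cf) <- dimnames(garr) <- list(NULL, nm, nm)
  list(h = h, c = cf, g = garr, converged = conv, residual = residual,
       iterations = it, gamma_star = gamma_star)
}

#' @export
print.pm_corr <- function(x, ...) {
  cat(sprintf(
    "HNC pair correlations: %d species, %d radial nodes (dr = %g A)\n",
    dim(x$g)[2], x$grid$n_points, x$grid$dr))
  cat(sprintf("  converged: %s (residual %.3g, %d iterations)\n",
              x$converged, x$residual, x$iterations))
  invisible(x)
}

#' @param x a \code{pm_corr} object.
#' @param pairs optional character matrix/vector of pair names to draw.
#' @param xlim radial range in angstrom.
#' @param ... passed to \code{matplot}.
#' @rdname solve_hnc
#' @export
plot.pm_corr <- function(x, pairs = NULL, xlim = c(0, 20), ...) {
  ns <- dim(x$g)[2]
  nm <- dimnames(x$g)[[2]]
  pidx <- .pair_index(ns)
  lab <- paste(nm[pidx[, 1]], nm[pidx[, 2]], sep = "-")
  y <- sapply(seq_len(nrow(pidx)),
              function(p) x$g[, pidx[p, 1], pidx[p, 2]])
  keep <- x$grid$r <= xlim[2]
  graphics::matplot(x$grid$r[keep], y[keep, , drop = FALSE], type = "l",
                    lty = 1, xlab = "r (A)", ylab = "g(r)", ...)
  graphics::legend("topright", legend = lab, lty = 1,
                   col = seq_along(lab), bty = "n")
  invisible(x)
}

## Quadratic (3-point Lagrange) extrapolation of g to contact from the
## first three nodes outside the core.
.contact_value <- function(r, g, d) {
  k <- which(r >= d)[1]
  if (is.na(k) || k + 2 > length(r)) return(NA_real_)
  rr <- r[k:(k + 2)]; gg <- g[k:(k + 2)]
  sum(gg * vapply(1:3, function(a) {
    o <- setdiff(1:3, a)
    prod((d - rr[o]) / (rr[a] - rr[o]))
  }, numeric(1)))
}

#' Excess Coulomb energy per particle from pair correlations
#'
#' Computes the reduced excess electrostatic energy beta*E_el/N =
#' (2 pi l_B / rho_tot) sum_ij rho_i rho_j z_i z_j int h_ij(r) r dr.
#' Writing the integrand with h rather than g makes it absolutely
#' convergent; by electroneutrality the two forms are identical, which
#' is how the long-range tail is handled exactly rather than truncated.
#'
#' @param corr a converged \code{pm_corr}.
#' @param model,state the model and state it was solved for (defaults to
#'   those stored in \code{corr}).
#' @return beta*E_el/N (dimensionless); 0 for uncharged systems.
#' @export
excess_coulomb_energy <- function(corr, model = corr$model,
                                  state = corr$state) {
  stopifnot(inherits(corr, "pm_corr"))
  if (!isTRUE(corr$converged))
    stop("refusing to evaluate energy on an unconverged solution")
  rho <- state$number_densities
  rho_tot <- sum(rho)
  if (rho_tot == 0) return(0)
  z <- unname(model$charge)
  lB <- bjerrum_length(model)
  r <- corr$grid$r
  ns <- length(rho)
  acc <- 0
  for (i in seq_len(ns)) for (j in seq_len(ns)) {
    if (z[i] == 0 || z[j] == 0) next
    f <- corr$h[, i, j] * r
    ## trapezoid including the [0, dr] segment (integrand -> 0 at r = 0)
    integral <- sum((f[-1] + f[-length(f)]) / 2) * corr$grid$dr +
      f[1] * corr$grid$dr / 2
    acc <- acc + rho[i] * rho[j] * z[i] * z[j] * integral
  }
  unname(2 * pi * lB / rho_tot * acc)
}

#' Osmotic coefficient via the virial route
#'
#' phi = 1 + (2 pi / 3 rho_tot) sum_ij rho_i rho_j d_ij^3 g_ij(d_ij+)
#'         + beta*E_el / (3N),
#' the exact virial expression for hard cores plus a 1/r potential.
#' Contact values g_ij(d_ij+) are obtained by three-point polynomial
#' extrapolation from the first grid nodes outside each core.
#'
#' @param corr a converged \code{pm_corr}.
#' @param model,state as in \code{\link{excess_coulomb_energy}}.
#' @return the osmotic coefficient (dimensionless); 1 at zero density.
#' @export
osmotic_coefficient <- function(corr, model = corr$model,
                                state = corr$state) {
  stopifnot(inherits(corr, "pm_corr"))
  if (!isTRUE(corr$converged))
    stop("refusing to evaluate phi on an unconverged solution")
  rho <- state$number_densities
  rho_tot <- sum(rho)
  if (rho_tot == 0) return(1)
  ns <- length(rho)
  r <- corr$grid$r
  contact <- 0
  for (i in seq_len(ns)) for (j in seq_len(ns)) {
    dij <- model$closest_approach[i, j]
    gc <- .contact_value(r, corr$g[, i, j], dij)
    contact <- contact + rho[i] * rho[j] * dij^3 * gc
  }
  unname(1 + 2 * pi / (3 * rho_tot) * contact +
         excess_coulomb_energy(corr, model, state) / 3)
}

#' Charge sum rule diagnostic
#'
#' For each species i returns the total screening charge
#' sum_j q_j rho_j int g_ij 4 pi r^2 dr, which should equal -q_i
#' (local electroneutrality) on a converged solution.
#'
#' @param corr a converged \code{pm_corr}.
#' @return named vector of screening charges, one per species.
#' @export
screening_charge <- function(corr) {
  stopifnot(inherits(corr, "pm_corr"))
  model <- corr$model
  rho <- corr$state$number_densities
  r <- corr$grid$r
  ns <- length(rho)
  out <- numeric(ns)
  for (i in seq_len(ns)) {
    s <- 0
    for (j in seq_len(ns)) {
      f <- corr$h[, i, j] * r^2          # h, not g: the background cancels
      integral <- sum((f[-1] + f[-length(f)]) / 2) * corr$grid$dr
      s <- s + model$charge[[j]] * rho[j] * 4 * pi * integral
    }
    out[i] <- s
  }
  stats::setNames(out, names(model$charge))
}
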