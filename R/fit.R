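## Fitting the cation hard-sphere diameter to an osmotic-coefficient
## curve, with the anion diameter held fixed and the cross diameter
## following from additivity.  This is the package's central model fit:
## fit_cation_diameter() returns a classed object with the usual
## print/summary/coef/predict/plot/residuals/simulate methods.

.binary_roles <- function(model) {
  q <- model$charge
  ci <- which(q > 0); ai <- which(q < 0)
  if (length(ci) != 1 || length(ai) != 1)
    stop("model template must contain exactly one cation and one anion")
  list(cation = ci, anion = ai)
}

## Salt stoichiometry from the ion charges, reduced so the smaller
## coefficient is 1 (symmetric salts give 1:1).
.salt_stoichiometry <- function(model) {
  r <- .binary_roles(model)
  zc <- model$charge[[r$cation]]; za <- abs(model$charge[[r$anion]])
  nu <- c(za, zc) / min(za, zc)
  stats::setNames(nu, names(model$charge)[c(r$cation, r$anion)])
}

.with_cation_diameter <- function(model, d_plus_plus) {
  r <- .binary_roles(model)
  sp <- model$species
  sp[[r$cation]]$diameter <- d_plus_plus
  pm_model(sp, epsilon_r = model$epsilon_r, temperature = model$temperature)
}

#' Predict an osmotic-coefficient curve from the primitive model
#'
#' Solves the HNC equations independently at each molality (each state
#' reached by the solver's deterministic coupling continuation, so the
#' result does not depend on evaluation order) and evaluates the
#' virial-route osmotic coefficient.  Molalities where the solver
#' fails are reported as NA and flagged, never fabricated.
#'
#' @param model_template a binary-salt \code{\link{pm_model}}; its anion
#'   diameter is kept, its cation diameter is replaced.
#' @param d_plus_plus cation hard-sphere diameter in angstrom, within
#'   [0.5, 10].
#' @param molalities increasing molalities in mol/kg.
#' @param grid \code{\link{radial_grid}} for the solver.
#' @param tolerance HNC convergence tolerance.
#' @return an \code{\link{osmotic_curve}} with attribute
#'   \code{failed_molalities}.
#' @export
predict_curve <- function(model_template, d_plus_plus, molalities,
                          grid = radial_grid(2^13, 0.025),
                          tolerance = 1e-7) {
  if (length(molalities) == 0)
    return(osmotic_curve(numeric(0), numeric(0)))
  if (d_plus_plus < 0.5 || d_plus_plus > 10)
    stop("'d_plus_plus' must lie within [0.5, 10] angstrom")
  model <- .with_cation_diameter(model_template, d_plus_plus)
  stoich <- .salt_stoichiometry(model)
  ## align the grid so the cation-anion contact sits exactly on a node:
  ## otherwise the effective hard-core diameter is rounded to the grid
  ## and phi acquires a sawtooth in d that biases the fit
  roles <- .binary_roles(model)
  d_pm <- model$closest_approach[roles$cation, roles$anion]
  n_node <- max(2, round(d_pm / grid$dr))
  dr_adj <- d_pm / n_node
  if (dr_adj > 0.05) dr_adj <- d_pm / (n_node + 1)
  grid <- radial_grid(grid$n_points, dr_adj)
  phi <- rep(NA_real_, length(molalities))
  failed <- numeric(0)
  for (k in seq_along(molalities)) {
    st <- molality_to_state(model, molalities[k], stoich)
    corr <- tryCatch(
      suppressWarnings(solve_hnc(model, st, grid, tolerance = tolerance)),
      hnc_nonconvergence = function(e) NULL)
    if (is.null(corr)) {
      failed <- c(failed, molalities[k])
      next
    }
    phi[k] <- osmotic_coefficient(corr)
  }
  if (all(is.na(phi)))
    stop("HNC failed at every molality: ",
         paste(signif(failed, 3), collapse = ", "))
  out <- osmotic_curve(molalities, phi)
  attr(out, "failed_molalities") <- failed
  out
}

#' Fit the cation diameter to an osmotic-coefficient curve
#'
#' Minimises the weighted sum of squared residuals
#' sum_k w_k (phi_model(m_k) - phi_k)^2 over the cation hard-sphere
#' diameter d_++ with the anion diameter fixed (taken from the model
#' template) and d_+- following from additivity.  A coarse scan over
#' the bounds locates the basin; bounded golden-section search
#' (\code{optimize}) refines it to \code{tol} angstrom.  Molalities
#' where the HNC solver fails are dropped from the objective with a
#' warning rather than penalised.
#'
#' @param curve an \code{\link{osmotic_curve}} with >= 3 points.
#' @param model_template binary-salt \code{\link{pm_model}} carrying the
#'   fixed anion diameter, permittivity and temperature.
#' @param bounds search interval for d_++ in angstrom.
#' @param weights per-point weights; default 1 (or 1/sigma^2 when the
#'   curve carries uncertainties and \code{weights = "sigma"}).
#' @param scan_step coarse-scan resolution in angstrom.
#' @param tol golden-section tolerance in angstrom.
#' @param grid,tolerance solver settings passed to
#'   \code{\link{predict_curve}}.
#' @return an object of class \code{ionpair_fit}.
#' @export
fit_cation_diameter <- function(curve, model_template,
                                bounds = c(1.5, 6.5), weights = NULL,
                                scan_step = 0.25, tol = 1e-3,
                                grid = radial_grid(2^13, 0.025),
                                tolerance = 1e-7) {
  stopifnot(inherits(curve, "osmotic_curve"))
  curve <- curve[!is.na(curve$phi), , drop = FALSE]
  if (nrow(curve) < 3) stop("need at least 3 usable curve points")
  w <- if (is.null(weights)) rep(1, nrow(curve))
       else if (identical(weights, "sigma")) {
         if (is.null(curve$sigma)) stop("curve carries no uncertainties")
         1 / curve$sigma^2
       } else weights
  n_eval <- 0L
  skipped_any <- new.env(parent = emptyenv()); skipped_any$m <- numeric(0)
  objective <- function(d) {
    n_eval <<- n_eval + 1L
    pred <- predict_curve(model_template, d, curve$molality, grid = grid,
                          tolerance = tolerance)
    ok <- !is.na(pred$phi)
    skipped_any$m <- union(skipped_any$m, curve$molality[!ok])
    if (sum(ok) < 3) return(NA_real_)
    sum(w[ok] * (pred$phi[ok] - curve$phi[ok])^2)
  }
  dscan <- seq(bounds[1], bounds[2], by = scan_step)
  fscan <- vapply(dscan, objective, numeric(1))
  if (all(is.na(fscan)))
    stop("objective not evaluable anywhere in the bounds (HNC failures)")
  k <- which.min(fscan)
  lo <- dscan[max(1, k - 1)]; hi <- dscan[min(length(dscan), k + 1)]
  opt <- stats::optimize(objective, lower = lo, upper = hi, tol = tol)
  d_best <- opt$minimum
  pred <- predict_curve(model_template, d_best, curve$molality,
                        grid = grid, tolerance = tolerance)
  ok <- !is.na(pred$phi)
  if (length(skipped_any$m))
    warning("HNC failed at molalities ",
            paste(signif(sort(skipped_any$m), 3), collapse = ", "),
            "; those points were dropped from the objective")
  roles <- .binary_roles(model_template)
  d_mm <- model_template$diameter[[roles$anion]]
  structure(list(
    d_plus_plus = d_best,
    d_minus_minus = d_mm,
    d_plus_minus = (d_best + d_mm) / 2,
    objective = opt$objective,
    residuals = data.frame(molality = curve$molality,
                           phi_obs = curve$phi,
                           phi_fit = pred$phi,
                           residual = pred$phi - curve$phi),
    weights = w,
    points_skipped = sort(skipped_any$m),
    n_evaluations = n_eval,
    scan = data.frame(d = dscan, objective = fscan),
    curve = curve,
    model_template = model_template,
    grid = grid,
    hnc_tolerance = tolerance),
    class = "ionpair_fit")
}

#' @export
print.ionpair_fit <- function(x, ...) {
  cat("Primitive-model cation diameter fit\n")
  cat(sprintf("  d_++ = %.3f A (d_-- fixed at %.3f A, d_+- = %.3f A)\n",
              x$d_plus_plus, x$d_minus_minus, x$d_plus_minus))
  cat(sprintf("  weighted SSE = %.4g over %d points (%d dropped)\n",
              x$objective, sum(!is.na(x$residuals$phi_fit)),
              length(x$points_skipped)))
  invisible(x)
}

#' @export
summary.ionpair_fit <- function(object, ...) {
  r <- object$residuals$residual
  cat("Primitive-model cation diameter fit\n\n")
  cat(sprintf("Fitted diameters (A):\n  d_++ = %.4f\n  d_-- = %.4f (fixed)\n  d_+- = %.4f (additivity)\n\n",
              object$d_plus_plus, object$d_minus_minus, object$d_plus_minus))
  cat(sprintf("Objective (weighted SSE): %.5g\n", object$objective))
  cat(sprintf("Residuals: min %.4g, median %.4g, max %.4g, RMS %.4g\n",
              min(r, na.rm = TRUE), stats::median(r, na.rm = TRUE),
              max(r, na.rm = TRUE), sqrt(mean(r^2, na.rm = TRUE))))
  cat(sprintf("Objective evaluations: %d\n", object$n_evaluations))
  if (length(object$points_skipped))
    cat("Molalities dropped (HNC failure): ",
        paste(signif(object$points_skipped, 3), collapse = ", "), "\n")
  invisible(object)
}

#' @export
coef.ionpair_fit <- function(object, ...) {
  c(d_plus_plus = object$d_plus_plus,
    d_minus_minus = object$d_minus_minus,
    d_plus_minus = object$d_plus_minus)
}

#' @export
residuals.ionpair_fit <- function(object, ...) {
  stats::setNames(object$residuals$residual, object$residuals$molality)
}

#' @param object an \code{ionpair_fit}.
#' @param molalities molalities at which to evaluate the fitted model;
#'   defaults to those of the fitted curve.
#' @rdname fit_cation_diameter
#' @export
predict.ionpair_fit <- function(object, molalities = NULL, ...) {
  if (is.null(molalities)) molalities <- object$residuals$molality
  predict_curve(object$model_template, object$d_plus_plus, molalities,
                grid = object$grid, tolerance = object$hnc_tolerance)
}

#' @export
plot.ionpair_fit <- function(x, ...) {
  df <- x$residuals
  graphics::plot(df$molality, df$phi_obs, pch = 1,
                 xlab = "molality (mol/kg)", ylab = expression(phi), ...)
  graphics::lines(df$molality, df$phi_fit, col = 2)
  graphics::legend("topleft", legend = c("data", "PM fit"),
                   pch = c(1, NA), lty = c(NA, 1), col = c(1, 2), bty = "n")
  invisible(x)
}

#' @export
simulate.ionpair_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  sd_hat <- sqrt(mean(object$residuals$residual^2, na.rm = TRUE))
  base <- object$residuals$phi_fit
  out <- lapply(seq_len(nsim), function(i)
    osmotic_curve(object$residuals$molality,
                  pmax(base + stats::rnorm(length(base), 0, sd_hat), 1e-6)))
  if (nsim == 1) out[[1]] else out
}
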