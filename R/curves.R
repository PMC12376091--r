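## Osmotic-coefficient curves: container and CSV round trip.

#' Osmotic-coefficient curve
#'
#' @param molality strictly increasing molalities, mol/kg, all > 0.
#' @param phi osmotic coefficients, > 0, same length.
#' @param label salt name.
#' @param sigma_phi optional per-point uncertainties.
#' @return an object of class \code{osmotic_curve} (a data frame with
#'   columns molality, phi and optionally sigma).
#' @export
osmotic_curve <- function(molality, phi, label = "", sigma_phi = NULL) {
  if (length(molality) != length(phi))
    stop("'molality' and 'phi' must have equal length")
  if (length(molality)) {
    if (any(molality <= 0)) stop("molalities must be > 0")
    if (any(diff(molality) <= 0)) stop("molalities must be strictly increasing")
    if (any(phi[!is.na(phi)] <= 0)) stop("phi must be > 0")
  }
  df <- data.frame(molality = molality, phi = phi)
  if (!is.null(sigma_phi)) {
    if (length(sigma_phi) != length(phi))
      stop("'sigma_phi' length mismatch")
    df$sigma <- sigma_phi
  }
  structure(df, label = label, class = c("osmotic_curve", "data.frame"))
}

#' Read an osmotic-coefficient curve from CSV
#'
#' Expects a header \code{molality,phi} with an optional third
#' \code{sigma} column.
#'
#' @param path CSV path.
#' @param label salt name (defaults to the file name).
#' @return an \code{\link{osmotic_curve}}.
#' @export
read_osmotic_curve <- function(path, label = basename(path)) {
  df <- utils::read.csv(path)
  need <- c("molality", "phi")
  if (!all(need %in% names(df)))
    stop("CSV must have columns 'molality' and 'phi'")
  osmotic_curve(df$molality, df$phi, label = label,
                sigma_phi = if ("sigma" %in% names(df)) df$sigma else NULL)
}

#' Write an osmotic-coefficient curve to CSV
#'
#' @param curve an \code{\link{osmotic_curve}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_osmotic_curve <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}
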