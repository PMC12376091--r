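## Particle configurations (positions, species labels, cubic periodic
## box, optional per-particle induced dipoles) and an extended-XYZ
## reader/writer.

#' Particle configuration in a cubic periodic box
#'
#' @param positions numeric matrix (n x 3) of coordinates in angstrom;
#'   wrapped into [0, box_length).
#' @param species character vector of per-particle species labels.
#' @param box_length cubic box edge in angstrom.
#' @param dipoles optional (n x 3) matrix of induced dipole vectors in
#'   debye; within any one species, either every particle carries a
#'   dipole row or none does.
#' @return an object of class \code{pm_config}.
#' @export
configuration <- function(positions, species, box_length, dipoles = NULL) {
  positions <- as.matrix(positions)
  if (length(positions) == 0) positions <- matrix(0, 0, 3)
  if (ncol(positions) != 3) stop("'positions' must have three columns")
  if (nrow(positions) != length(species))
    stop("one species label per particle required")
  if (!is.finite(box_length) || box_length <= 0)
    stop("'box_length' must be > 0")
  positions <- positions - box_length * floor(positions / box_length)
  if (!is.null(dipoles)) {
    dipoles <- as.matrix(dipoles)
    if (nrow(dipoles) != nrow(positions) || ncol(dipoles) != 3)
      stop("'dipoles' must be an n x 3 matrix matching 'positions'")
    has <- rowSums(is.na(dipoles)) == 0
    for (s in unique(species)) {
      hs <- has[species == s]
      if (any(hs) && !all(hs))
        stop("species ", s, " has dipoles on some particles only")
    }
  }
  structure(list(positions = positions, species = as.character(species),
                 box_length = box_length, dipoles = dipoles),
            class = "pm_config")
}

#' @export
print.pm_config <- function(x, ...) {
  tab <- table(x$species)
  cat(sprintf("Configuration: %d particles in L = %.4g A box (%s)%s\n",
              nrow(x$positions), x$box_length,
              paste(names(tab), tab, sep = ":", collapse = ", "),
              if (is.null(x$dipoles)) "" else ", with dipoles"))
  invisible(x)
}

## Minimum-image displacement matrix helpers.
.min_image <- function(d, L) d - L * round(d / L)

## All minimum-image distances between rows of A and rows of B.
.pair_distances <- function(A, B, L) {
  dx <- .min_image(outer(A[, 1], B[, 1], `-`), L)
  dy <- .min_image(outer(A[, 2], B[, 2], `-`), L)
  dz <- .min_image(outer(A[, 3], B[, 3], `-`), L)
  sqrt(dx^2 + dy^2 + dz^2)
}

#' Read configurations from an extended-XYZ file
#'
#' Dialect: per frame, a particle count line, a comment line carrying
#' \code{box=L}, then one line per particle with \code{species x y z}
#' and optionally \code{mux muy muz} (induced dipole, debye).
#'
#' @param path file path.
#' @return a list of \code{\link{configuration}} objects, one per frame.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- as.integer(trimws(lines[i]))
    if (is.na(n)) stop("bad particle count at line ", i)
    comment <- lines[i + 1L]
    bm <- regmatches(comment, regexpr("box=[0-9eE+.-]+", comment))
    if (!length(bm)) stop("frame comment lacks box=L: ", comment)
    L <- as.numeric(sub("box=", "", bm))
    rows <- lines[(i + 2L):(i + 1L + n)]
    tok <- strsplit(trimws(rows), "[[:space:]]+")
    ncol_row <- lengths(tok)
    if (!all(ncol_row %in% c(4L, 7L)))
      stop("particle lines must have 4 or 7 fields")
    sp <- vapply(tok, `[[`, character(1), 1)
    num <- t(vapply(tok, function(tk) as.numeric(tk[-1]),
                    numeric(ncol_row[1] - 1L)))
    dip <- if (ncol_row[1] == 7L) num[, 4:6, drop = FALSE] else NULL
    frames[[length(frames) + 1L]] <-
      configuration(num[, 1:3, drop = FALSE], sp, L, dipoles = dip)
    i <- i + 2L + n
  }
  frames
}

#' Write configurations to an extended-XYZ file
#'
#' Coordinates and dipoles are printed with \%.17g so that a read/write
#' cycle reproduces the doubles bit for bit.
#'
#' @param frames a \code{\link{configuration}} or list of them.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_xyz <- function(frames, path) {
  if (inherits(frames, "pm_config")) frames <- list(frames)
  con <- file(path, "w"); on.exit(close(con))
  for (fr in frames) {
    n <- nrow(fr$positions)
    writeLines(c(as.character(n), sprintf("box=%.17g", fr$box_length)), con)
    if (n == 0) next
    if (is.null(fr$dipoles)) {
      writeLines(sprintf("%s %.17g %.17g %.17g", fr$species,
                         fr$positions[, 1], fr$positions[, 2],
                         fr$positions[, 3]), con)
    } else {
      writeLines(sprintf("%s %.17g %.17g %.17g %.17g %.17g %.17g",
                         fr$species,
                         fr$positions[, 1], fr$positions[, 2],
                         fr$positions[, 3],
                         fr$dipoles[, 1], fr$dipoles[, 2],
                         fr$dipoles[, 3]), con)
    }
  }
  invisible(path)
}
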