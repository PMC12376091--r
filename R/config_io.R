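## Flat TOML-style model definition files.
##
## Supported dialect: comments (#), [model] section with scalar keys,
## repeated [[species]] blocks.  Values: numbers, quoted strings,
## true/false.  This covers the model-definition files the package
## ships and writes; it is not a general TOML parser.

.parse_flat_toml <- function(lines) {
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  cur <- NULL          # character path of current table
  arr <- FALSE
  for (ln in lines) {
    if (grepl("^\\[\\[.+\\]\\]$", ln)) {
      cur <- gsub("^\\[\\[|\\]\\]$", "", ln)
      arr <- TRUE
      out[[cur]] <- c(out[[cur]], list(list()))
    } else if (grepl("^\\[.+\\]$", ln)) {
      cur <- gsub("^\\[|\\]$", "", ln)
      arr <- FALSE
      if (is.null(out[[cur]])) out[[cur]] <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      kv <- regmatches(ln, regexpr("=", ln, fixed = TRUE), invert = TRUE)[[1]]
      key <- trimws(kv[1]); val <- trimws(kv[2])
      if (grepl('^".*"$', val)) {
        val <- gsub('^"|"$', "", val)
      } else if (val %in% c("true", "false")) {
        val <- identical(val, "true")
      } else {
        num <- suppressWarnings(as.numeric(val))
        if (!is.na(num)) val <- num
      }
      if (is.null(cur)) {
        out[[key]] <- val
      } else if (arr) {
        n <- length(out[[cur]])
        out[[cur]][[n]][[key]] <- val
      } else {
        out[[cur]][[key]] <- val
      }
    } else {
      stop("cannot parse config line: ", ln)
    }
  }
  out
}

#' Read a primitive-model definition file
#'
#' The file is a flat TOML-style config with one \code{[model]} section
#' (keys \code{epsilon_r}, \code{temperature_K}) and one
#' \code{[[species]]} block per species (keys \code{name},
#' \code{charge}, \code{diameter_A}, optional \code{alpha_prime_A3}).
#' Any other sections (e.g. force-field metadata tables) are returned
#' unparsed in the \code{extra} attribute.
#'
#' @param path path to the config file.
#' @return a \code{\link{pm_model}}.
#' @export
read_pm_model <- function(path) {
  cfg <- .parse_flat_toml(readLines(path, warn = FALSE))
  if (is.null(cfg$species)) stop("config has no [[species]] blocks: ", path)
  sp <- lapply(cfg$species, function(s) {
    pm_species(name = s$name, charge = s$charge, diameter = s$diameter_A,
               polarizability_volume = if (is.null(s$alpha_prime_A3)) 0
                                       else s$alpha_prime_A3)
  })
  md <- cfg$model
  if (is.null(md)) stop("config has no [model] section: ", path)
  m <- pm_model(sp,
                epsilon_r = md$epsilon_r,
                temperature = if (is.null(md$temperature_K)) 298.15
                              else md$temperature_K)
  extra <- cfg[setdiff(names(cfg), c("model", "species"))]
  if (length(extra)) attr(m, "extra") <- extra
  m
}

#' Write a primitive-model definition file
#'
#' @param model a \code{\link{pm_model}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_pm_model <- function(model, path) {
  stopifnot(inherits(model, "pm_model"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("[model]",
               sprintf("epsilon_r = %.17g", model$epsilon_r),
               sprintf("temperature_K = %.17g", model$temperature), ""), con)
  for (s in model$species) {
    writeLines(c("[[species]]",
                 sprintf('name = "%s"', s$name),
                 sprintf("charge = %.17g", s$charge),
                 sprintf("diameter_A = %.17g", s$diameter),
                 sprintf("alpha_prime_A3 = %.17g", s$polarizability_volume),
                 ""), con)
  }
  invisible(path)
}
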