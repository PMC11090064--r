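#' Refraction per gram from refractive index and mass density
#'
#' The Lorentz-Lorenz (Clausius-Mossotti) relation links the specific
#' refractivity \eqn{R} of a substance to its refractive index \eqn{n} and
#' mass density \eqn{\rho}:
#' \deqn{R = \frac{1}{\rho}\,\frac{n^2 - 1}{n^2 + 2}.}
#' \eqn{R} is proportional to the polarizability per unit molar mass and is,
#' to a good approximation, an additive material constant.
#'
#' @param n refractive index (dimensionless), \code{n >= 1}
#' @param rho mass density in g/mL, \code{rho > 0}
#' @return refraction per gram in mL/g
#' @seealso [ri_from_material()] for the inverse
#' @export
#' @examples
#' refraction_per_gram(1.333, 0.997) # water, about 0.206 mL/g
refraction_per_gram <- function(n, rho) {
  stopifnot(is.numeric(n), is.numeric(rho))
  if (any(rho <= 0)) stop("mass density must be positive")
  if (any(n < 1)) stop("refractive index must be >= 1")
  (1 / rho) * (n^2 - 1) / (n^2 + 2)
}

#' Refractive index from refraction per gram and mass density
#'
#' Inverts the Lorentz-Lorenz relation:
#' \deqn{n = \sqrt{\frac{1 + 2 R \rho}{1 - R \rho}}.}
#' The product \eqn{R\rho} must be below 1; the closed form has a pole there
#' and larger values are nonphysical.
#'
#' @param R refraction per gram in mL/g
#' @param rho mass density in g/mL
#' @return refractive index (dimensionless)
#' @export
#' @examples
#' ri_from_material(0.2063, 0.997) # about 1.333
ri_from_material <- function(R, rho) {
  stopifnot(is.numeric(R), is.numeric(rho))
  if (any(rho <= 0)) stop("mass density must be positive")
  if (any(R < 0)) stop("refraction per gram must be non-negative")
  x <- R * rho
  if (any(x >= 1)) stop("nonphysical refractivity: R * rho must be < 1")
  sqrt((1 + 2 * x) / (1 - x))
}

#' Solvent description
#'
#' The solvent (water, in biological matter) is treated as exactly known:
#' its refractive index \code{n1} and mass density \code{rho1} carry no
#' uncertainty. Defaults are water at room temperature with the sodium-D
#' refractive index.
#'
#' @param n1 solvent refractive index, default 1.3330
#' @param rho1 solvent mass density in g/mL, default 0.997
#' @return an object of class \code{"solvent"}
#' @export
solvent <- function(n1 = 1.3330, rho1 = 0.997) {
  stopifnot(is.numeric(n1), length(n1) == 1L, is.numeric(rho1), length(rho1) == 1L)
  if (n1 <= 1) stop("solvent refractive index must be > 1")
  if (rho1 <= 0) stop("solvent mass density must be positive")
  structure(list(n1 = n1, rho1 = rho1), class = "solvent")
}

#' @export
print.solvent <- function(x, ...) {
  cat(sprintf("Solvent: n1 = %.4f, rho1 = %.4f g/mL\n", x$n1, x$rho1))
  invisible(x)
}

#' Material constants
#'
#' A material is characterised by its refraction per gram \code{R} (mL/g)
#' and partial specific volume (PSV) \code{theta} (mL/g), from which its
#' pure density \code{rho = 1/theta} and refractive index \code{n} (via the
#' Lorentz-Lorenz relation) follow under volume additivity. Either
#' \code{(R, theta)} or \code{(n, rho)} may be supplied; the other pair is
#' derived. Optional standard deviations \code{dR} and \code{dtheta}
#' describe material heterogeneity (0 = exactly known).
#'
#' @param name label for the material
#' @param R refraction per gram, mL/g
#' @param theta partial specific volume, mL/g
#' @param n pure-substance refractive index (alternative input)
#' @param rho pure-substance mass density, g/mL (alternative input)
#' @param dR standard deviation of \code{R}, mL/g
#' @param dtheta standard deviation of \code{theta}, mL/g
#' @param provenance free-text citation for the constants
#' @return an object of class \code{"material"} with fields
#'   \code{name, R, theta, dR, dtheta, n, rho, provenance}
#' @export
#' @examples
#' material("triolein", n = 1.4676, rho = 0.9078)
material <- function(name, R = NULL, theta = NULL, n = NULL, rho = NULL,
                     dR = 0, dtheta = 0, provenance = "") {
  from_nrho <- !is.null(n) && !is.null(rho)
  from_Rtheta <- !is.null(R) && !is.null(theta)
  if (!from_nrho && !from_Rtheta)
    stop(sprintf("material '%s': supply either (R, theta) or (n, rho)", name))
  if (from_nrho && !from_Rtheta) {
    if (rho <= 0) stop(sprintf("material '%s': rho must be positive", name))
    if (n <= 1) stop(sprintf("material '%s': n must be > 1", name))
    R <- refraction_per_gram(n, rho)
    theta <- 1 / rho
  } else {
    if (theta <= 0) stop(sprintf("material '%s': theta must be positive", name))
    if (R < 0) stop(sprintf("material '%s': R must be >= 0", name))
    if (R / theta >= 1)
      stop(sprintf("material '%s': R/theta must be < 1 (Lorentz-Lorenz domain)", name))
    rho <- 1 / theta
    n <- ri_from_material(R, rho)
  }
  if (dR < 0 || dtheta < 0) stop("standard deviations must be >= 0")
  structure(list(name = name, R = R, theta = theta, dR = dR, dtheta = dtheta,
                 n = n, rho = rho, provenance = provenance),
            class = "material")
}

#' @export
print.material <- function(x, ...) {
  cat(sprintf("Material '%s': R = %.4f mL/g, theta = %.4f mL/g (n = %.4f, rho = %.4f g/mL)\n",
              x$name, x$R, x$theta, x$n, x$rho))
  if (x$dR > 0 || x$dtheta > 0)
    cat(sprintf("  spread: dR = %.4g, dtheta = %.4g mL/g\n", x$dR, x$dtheta))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

# YAML 1.1 parses a bare `n:` key as the boolean FALSE; restore it.
.fix_yaml_n <- function(e) {
  if (is.list(e) && !is.null(names(e)))
    names(e)[names(e) == "FALSE"] <- "n"
  e
}

#' Load a material table
#'
#' Reads a nested-mapping YAML file of material constants. Each entry may
#' give \code{(R, theta)} or \code{(n, rho)} (plus optional \code{dR},
#' \code{dtheta}, \code{provenance}); see the bundled table at
#' \code{system.file("extdata", "materials.yaml", package = "ridens")} for
#' the format. The bundled constants (water, triolein, milk components,
#' soybean oil, common phospholipid fatty acids) are literature stand-ins
#' carrying per-entry citations and can be overridden by supplying a
#' user file.
#'
#' @param path YAML file; default is the bundled table
#' @return an object of class \code{"material_table"}: a named list of
#'   [material()] objects
#' @export
material_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "materials.yaml", package = "ridens")
  if (!file.exists(path)) stop("material table file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (length(raw) == 0L)
    return(structure(list(), class = "material_table"))
  if (is.null(names(raw)) || anyDuplicated(names(raw)))
    stop("material table entries must have unique names")
  entries <- lapply(names(raw), function(nm) {
    e <- .fix_yaml_n(raw[[nm]])
    if (!is.list(e)) stop(sprintf("entry '%s': expected a mapping", nm))
    tryCatch(
      material(nm,
               R = e$R, theta = e$theta, n = e$n, rho = e$rho,
               dR = if (is.null(e$dR)) 0 else e$dR,
               dtheta = if (is.null(e$dtheta)) 0 else e$dtheta,
               provenance = if (is.null(e$provenance)) "" else e$provenance),
      error = function(err)
        stop(sprintf("material table entry '%s': %s", nm, conditionMessage(err)),
             call. = FALSE))
  })
  names(entries) <- names(raw)
  structure(entries, class = "material_table")
}

#' @export
print.material_table <- function(x, ...) {
  cat(sprintf("Material table with %d entries\n", length(x)))
  for (m in x) print(m)
  invisible(x)
}

#' @export
#' @method as.data.frame material_table
as.data.frame.material_table <- function(x, ...) {
  if (length(x) == 0L)
    return(data.frame(name = character(), R = numeric(), dR = numeric(),
                      theta = numeric(), dtheta = numeric(), n = numeric(),
                      rho = numeric(), provenance = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, lapply(unclass(x), function(m)
    data.frame(name = m$name, R = m$R, dR = m$dR, theta = m$theta,
               dtheta = m$dtheta, n = m$n, rho = m$rho,
               provenance = m$provenance, stringsAsFactors = FALSE)))
}

#' Export a material table as CSV
#'
#' @param x a \code{material_table}
#' @param path output CSV path
#' @return \code{path}, invisibly
#' @export
write_material_csv <- function(x, path) {
  stopifnot(inherits(x, "material_table"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
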