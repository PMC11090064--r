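#' Solution mass density from solute concentration
#'
#' Under volume additivity a binary solution with solvent density
#' \code{rho1} and solute of partial specific volume (PSV) \code{theta} at
#' concentration \code{c2} has
#' \deqn{\rho = \rho_1 (1 - c_2 \theta) + c_2.}
#'
#' @param c2 solute concentration, g/mL (mass per solution volume)
#' @param theta solute PSV, mL/g
#' @param rho1 solvent density, g/mL
#' @return solution density, g/mL
#' @export
rho_from_concentration <- function(c2, theta, rho1) {
  stopifnot(is.numeric(c2), is.numeric(theta), is.numeric(rho1))
  if (any(c2 < 0)) stop("concentration must be non-negative")
  if (any(c2 * theta > 1 + 1e-12))
    stop("c2 * theta > 1: solute volume exceeds sample volume under additivity")
  rho1 * (1 - c2 * theta) + c2
}

#' RI contrast from solute concentration
#'
#' The RI contrast against the solvent is linear in concentration,
#' \eqn{\delta n = \alpha c_2}, with RI increment \eqn{\alpha = \partial n /
#' \partial c_2}.
#'
#' @param c2 solute concentration, g/mL
#' @param alpha RI increment, mL/g
#' @return RI contrast (dimensionless)
#' @export
contrast_from_concentration <- function(c2, alpha) {
  stopifnot(is.numeric(c2), is.numeric(alpha))
  if (any(c2 < 0)) stop("concentration must be non-negative")
  alpha * c2
}

#' RI increment under the Biot mixing rule
#'
#' The Biot (arithmetic volume-average) mixing rule with volume additivity
#' gives \eqn{\alpha = \theta (n_2 - n_1)}: a solute of PSV \code{theta} and
#' pure refractive index \code{n2} in a solvent of index \code{n1}.
#'
#' @param theta solute PSV, mL/g
#' @param n2 solute refractive index
#' @param n1 solvent refractive index
#' @return RI increment, mL/g (negative if \code{n2 < n1})
#' @export
alpha_biot <- function(theta, n2, n1) {
  stopifnot(is.numeric(theta), is.numeric(n2), is.numeric(n1))
  if (any(theta <= 0)) stop("theta must be positive")
  theta * (n2 - n1)
}

#' Mass density from RI contrast (Biot rule, closed form)
#'
#' The central estimator: the linear density-RI relation
#' \deqn{\rho(\delta n) = \frac{\delta n}{\alpha} +
#'   \rho_1\left(1 - \theta \frac{\delta n}{\alpha}\right),}
#' with slope \eqn{\partial\rho/\partial n = (1 - \rho_1\theta)/\alpha}.
#' A negative \code{dn} implies a negative concentration; measured RI
#' contrasts can fluctuate below zero, so the value is still returned with a
#' warning.
#'
#' @param dn RI contrast \eqn{n - n_1}
#' @param alpha RI increment, mL/g (non-zero)
#' @param theta PSV, mL/g
#' @param rho1 solvent density, g/mL
#' @return mass density, g/mL
#' @export
#' @examples
#' rho_from_contrast(1.3655 - 1.3330, 0.1971, 0.734, 0.997)
rho_from_contrast <- function(dn, alpha, theta, rho1) {
  stopifnot(is.numeric(dn), is.numeric(alpha), is.numeric(theta), is.numeric(rho1))
  if (any(alpha == 0)) stop("alpha = 0: density is decoupled from RI (degenerate model)")
  c2 <- dn / alpha
  if (any(c2 < 0)) warning("dn/alpha < 0 implies a negative concentration; returning extrapolated density")
  if (any(c2 * theta > 1 + 1e-12)) stop("implied solute volume fraction exceeds 1")
  c2 + rho1 * (1 - theta * c2)
}

#' Biot mixing rule
#'
#' Volume-fraction weighted arithmetic mean of component refractive
#' indices: \eqn{n = \sum_i \phi_i n_i}.
#'
#' @param phis volume fractions (non-negative, summing to 1)
#' @param ns component refractive indices, same length
#' @return mixture refractive index
#' @export
biot_mix <- function(phis, ns) {
  stopifnot(length(phis) == length(ns))
  if (any(phis < 0)) stop("volume fractions must be non-negative")
  if (abs(sum(phis) - 1) > 1e-9) stop("volume fractions must sum to 1")
  sum(phis * ns)
}

#' Mass fractions from relative volume fractions
#'
#' For equal-volume voxelinos a voxelino of PSV \eqn{\theta_i} carries mass
#' \eqn{v_0/\theta_i}, so relative volume fractions \code{x} convert to
#' relative mass fractions as
#' \deqn{y_j = \frac{x_j/\theta_j}{\sum_k x_k/\theta_k}.}
#'
#' @param x relative volume fractions (sum to 1)
#' @param thetas PSVs, mL/g
#' @return mass fractions summing to 1
#' @export
mass_from_volume_weights <- function(x, thetas) {
  stopifnot(length(x) == length(thetas))
  if (any(x < 0)) stop("volume fractions must be non-negative")
  if (abs(sum(x) - 1) > 1e-9) stop("volume fractions must sum to 1")
  if (any(thetas <= 0)) stop("thetas must be positive")
  w <- x / thetas
  w / sum(w)
}

#' Effective mixture parameters (means)
#'
#' The effective PSV and RI increment of a composite solute are the
#' mass-fraction weighted averages of the component parameters:
#' \eqn{\theta_{\mathrm{eff}} = \sum_i y_i \theta_i},
#' \eqn{\alpha_{\mathrm{eff}} = \sum_i y_i \alpha_i}. They absorb the
#' compositional complexity while the binary-model relations retain their
#' form.
#'
#' @param y mass fractions (sum to 1)
#' @param alphas component RI increments, mL/g
#' @param thetas component PSVs, mL/g
#' @return list with \code{alpha_eff} and \code{theta_eff}, mL/g
#' @export
effective_params <- function(y, alphas, thetas) {
  stopifnot(length(y) == length(alphas), length(y) == length(thetas))
  if (abs(sum(y) - 1) > 1e-9) stop("mass fractions must sum to 1")
  list(alpha_eff = sum(y * alphas), theta_eff = sum(y * thetas))
}

#' Effective PSV of a binary solute at a given lipid volume fraction
#'
#' For two components at relative volume fractions \code{(1 - x_lip, x_lip)}
#' the mass-averaged effective PSV reduces to the volume-weighted harmonic
#' mean
#' \deqn{\bar\theta_{\mathrm{eff}}(x) =
#'   \left(\frac{x}{\theta_b} + \frac{1 - x}{\theta_a}\right)^{-1},}
#' where component b is the lipid.
#'
#' @param x_lip relative lipid volume fraction in \[0, 1\]
#' @param theta_a PSV of component a (e.g. protein), mL/g
#' @param theta_b PSV of component b (e.g. lipid), mL/g
#' @return effective PSV, mL/g
#' @export
binary_effective_theta <- function(x_lip, theta_a, theta_b) {
  stopifnot(is.numeric(x_lip))
  if (any(x_lip < 0 | x_lip > 1)) stop("x_lip must lie in [0, 1]")
  if (theta_a <= 0 || theta_b <= 0) stop("thetas must be positive")
  1 / (x_lip / theta_b + (1 - x_lip) / theta_a)
}

#' Density-RI decoupling composition
#'
#' Solves \eqn{\bar\theta_{\mathrm{eff}}(x^\ast) = 1/\rho_1} for the lipid
#' volume fraction at which the slope \eqn{\partial\rho/\partial n} of the
#' density-RI relation vanishes: the mass density becomes insensitive to
#' the RI (and to the solvent content). Requires \eqn{1/\rho_1} to lie
#' strictly between the two component PSVs.
#'
#' @param theta_p PSV of the protein-like component, mL/g
#' @param theta_lip PSV of the lipid component, mL/g
#' @param rho1 solvent density, g/mL
#' @return the decoupling volume fraction \eqn{x^\ast \in (0, 1)}
#' @export
#' @examples
#' decoupling_fraction(0.734, 1 / 0.9078, 0.997) # about 0.80
decoupling_fraction <- function(theta_p, theta_lip, rho1) {
  if (theta_p <= 0 || theta_lip <= 0 || rho1 <= 0) stop("parameters must be positive")
  # theta_eff(x) = 1/rho1  <=>  x/theta_lip + (1-x)/theta_p = rho1
  x <- (rho1 - 1 / theta_p) / (1 / theta_lip - 1 / theta_p)
  if (!is.finite(x) || x < 0 || x > 1)
    stop("composition cannot decouple: 1/rho1 does not lie between the component PSVs")
  x
}

# Lorentz-Lorenz function L(n) = (n^2-1)/(n^2+2) and inverse; internal.
ll_of_n <- function(n) (n^2 - 1) / (n^2 + 2)
n_of_ll <- function(L) {
  if (any(L >= 1)) stop("Lorentz-Lorenz value must be < 1")
  sqrt((1 + 2 * L) / (1 - L))
}

#' RI increment in the dilute limit of the Wiener mixing rule
#'
#' For a solute of refraction per gram \code{R} and PSV \code{theta}, the
#' pure-solute index \eqn{n_2} follows from the Lorentz-Lorenz relation at
#' density \eqn{1/\theta}; the Wiener effective-medium rule then gives, in
#' the dilute limit \eqn{n \to n_1},
#' \deqn{\alpha_W = \frac{3}{2}\,\theta\, n_1\,
#'   \frac{n_2^2 - n_1^2}{n_2^2 + 2 n_1^2}.}
#' This is systematically below the Biot value \eqn{\theta (n_2 - n_1)}
#' for \eqn{n_2 > n_1}.
#'
#' @param R refraction per gram, mL/g
#' @param theta PSV, mL/g
#' @param n1 solvent refractive index
#' @return dilute-limit RI increment, mL/g
#' @export
alpha_wiener_dilute <- function(R, theta, n1) {
  n2 <- ri_from_material(R, 1 / theta)
  1.5 * theta * n1 * (n2^2 - n1^2) / (n2^2 + 2 * n1^2)
}

#' Solute composition
#'
#' Bundles solute components with their relative volume fractions and the
#' per-component RI increment (Biot) and PSV, referenced to a solvent.
#' Components may be [material()] objects (alpha derived as
#' \code{theta * (n - n1)}; spreads propagated from \code{dR}, \code{dtheta})
#' or plain lists with fields \code{name, alpha, theta} and optional
#' \code{dalpha, dtheta}.
#'
#' @param components list of materials or parameter lists
#' @param x relative volume fractions (sum to 1)
#' @param solvent a [solvent()] object
#' @return object of class \code{"solute_composition"} with per-component
#'   vectors \code{alpha, theta, dalpha, dtheta, n, x}
#' @export
solute_composition <- function(components, x, solvent = ridens::solvent()) {
  stopifnot(inherits(solvent, "solvent"), length(components) == length(x))
  if (any(x < 0)) stop("volume fractions must be non-negative")
  if (abs(sum(x) - 1) > 1e-9) stop("volume fractions must sum to 1")
  comp <- lapply(components, function(m) {
    if (inherits(m, "material")) {
      n2 <- m$n
      a <- alpha_biot(m$theta, n2, solvent$n1)
      # first-order propagation of (dR, dtheta) into (dalpha, dtheta):
      # n2 = n2(R, rho=1/theta); dn2/dR = rho (n2^2+2)^2 / (6 n2) etc.
      dn2_dR <- if (m$dR > 0) (1 / m$theta) * (n2^2 + 2)^2 / (6 * n2) else 0
      # rho = 1/theta -> dn2/dtheta = dn2/drho * (-1/theta^2)
      dn2_drho <- m$R * (n2^2 + 2)^2 / (6 * n2)
      dn2_dth <- -dn2_drho / m$theta^2
      da <- sqrt((m$theta * dn2_dR * m$dR)^2 +
                 ((n2 - solvent$n1) + m$theta * dn2_dth)^2 * m$dtheta^2)
      list(name = m$name, alpha = a, theta = m$theta,
           dalpha = da, dtheta = m$dtheta, n = n2)
    } else {
      stopifnot(!is.null(m$alpha), !is.null(m$theta))
      if (m$theta <= 0) stop("component theta must be positive")
      list(name = if (is.null(m$name)) "component" else m$name,
           alpha = m$alpha, theta = m$theta,
           dalpha = if (is.null(m$dalpha)) 0 else m$dalpha,
           dtheta = if (is.null(m$dtheta)) 0 else m$dtheta,
           n = solvent$n1 + m$alpha / m$theta)
    }
  })
  structure(list(
    name   = vapply(comp, `[[`, character(1), "name"),
    alpha  = vapply(comp, `[[`, numeric(1), "alpha"),
    theta  = vapply(comp, `[[`, numeric(1), "theta"),
    dalpha = vapply(comp, `[[`, numeric(1), "dalpha"),
    dtheta = vapply(comp, `[[`, numeric(1), "dtheta"),
    n      = vapply(comp, `[[`, numeric(1), "n"),
    x      = x,
    solvent = solvent
  ), class = "solute_composition")
}

#' @export
print.solute_composition <- function(x, ...) {
  eff <- composition_effective(x)
  cat(sprintf("Solute composition (%d components):\n", length(x$name)))
  for (i in seq_along(x$name))
    cat(sprintf("  %-14s x = %.3f  alpha = %.4f  theta = %.4f mL/g\n",
                x$name[i], x$x[i], x$alpha[i], x$theta[i]))
  cat(sprintf("  effective: alpha_eff = %.4f, theta_eff = %.4f mL/g\n",
              eff$alpha_eff, eff$theta_eff))
  invisible(x)
}

#' Effective parameters of a solute composition
#'
#' Mass-averaged effective RI increment and PSV of a
#' [solute_composition()], using the volume-to-mass weight conversion for
#' equal-volume voxelinos.
#'
#' @param comp a \code{solute_composition}
#' @return list with \code{alpha_eff}, \code{theta_eff} (mL/g) and the mass
#'   fractions \code{y}
#' @export
composition_effective <- function(comp) {
  stopifnot(inherits(comp, "solute_composition"))
  y <- mass_from_volume_weights(comp$x, comp$theta)
  e <- effective_params(y, comp$alpha, comp$theta)
  e$y <- y
  e
}

# Solution RI as a function of concentration under a named mixing rule.
# The solute aggregate (n2, theta_eff) is formed per rule: Biot aggregates
# component RIs by volume; the other rules aggregate the Lorentz-Lorenz
# refractivity by volume (equivalent to mass-averaging R).
n_of_c <- function(c2, rule, comp) {
  sv <- comp$solvent
  theta_eff <- composition_effective(comp)$theta_eff
  phi2 <- c2 * theta_eff
  if (any(phi2 > 1 + 1e-12)) stop("concentration exceeds the packing limit 1/theta_eff")
  n2 <- switch(rule,
    biot = sum(comp$x * comp$n),
    lorentz_lorenz = ,
    wiener = n_of_ll(sum(comp$x * ll_of_n(comp$n))),
    stop("unknown mixing rule: ", rule))
  switch(rule,
    biot = (1 - phi2) * sv$n1 + phi2 * n2,
    lorentz_lorenz = n_of_ll((1 - phi2) * ll_of_n(sv$n1) + phi2 * ll_of_n(n2)),
    wiener = {
      # (n^2 - n1^2)/(n^2 + 2 n1^2) = phi2 (n2^2 - n1^2)/(n2^2 + 2 n1^2)
      g <- phi2 * (n2^2 - sv$n1^2) / (n2^2 + 2 * sv$n1^2)
      sqrt(sv$n1^2 * (1 + 2 * g) / (1 - g))
    })
}

#' Mass density from RI contrast under a generic mixing rule
#'
#' For mixing rules other than Biot no closed-form density-RI relation is
#' used; instead the rule's \eqn{n(c_2)} is inverted for the concentration by
#' bracketed root finding on \eqn{c_2 \in [0, 1/\theta_{\mathrm{eff}}]}
#' (tolerance 1e-12) and the result substituted into the density relation.
#' For \code{rule = "biot"} this agrees with [rho_from_contrast()] to
#' 1e-10.
#'
#' @param dn RI contrast (scalar or vector)
#' @param rule one of \code{"biot"}, \code{"lorentz_lorenz"}, \code{"wiener"}
#' @param comp a [solute_composition()]
#' @return mass density, g/mL
#' @export
rho_from_contrast_generic <- function(dn, rule = c("biot", "lorentz_lorenz", "wiener"),
                                      comp, solvent = NULL) {
  rule <- match.arg(rule)
  stopifnot(inherits(comp, "solute_composition"))
  if (!is.null(solvent)) comp$solvent <- solvent
  sv <- comp$solvent
  theta_eff <- composition_effective(comp)$theta_eff
  c_max <- 1 / theta_eff
  n_max <- n_of_c(c_max, rule, comp)
  vapply(dn, function(d) {
    if (d < 0) {
      warning("negative RI contrast; extrapolating below zero concentration")
      # linearized extrapolation using the dilute-limit increment
      a0 <- (n_of_c(1e-8, rule, comp) - sv$n1) / 1e-8
      return(rho_from_concentration(0, theta_eff, sv$rho1) + d / a0 * (1 - sv$rho1 * theta_eff))
    }
    if (d > n_max - sv$n1 + 1e-12)
      stop("RI contrast outside the attainable range for this rule/composition")
    c2 <- if (d == 0) 0 else
      stats::uniroot(function(cc) n_of_c(cc, rule, comp) - (sv$n1 + d),
                     lower = 0, upper = c_max, tol = 1e-12)$root
    rho_from_concentration(c2, theta_eff, sv$rho1)
  }, numeric(1))
}
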