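#' Combine systematic and statistical uncertainties
#'
#' Root-sum-square combination \eqn{\Delta z = \sqrt{\Delta z_{sys}^2 +
#' \Delta z_{stat}^2}} of independent uncertainty components.
#'
#' @param sys systematic standard deviation (>= 0)
#' @param stat statistical standard deviation (>= 0)
#' @return combined standard deviation
#' @export
combine_uncertainties <- function(sys, stat) {
  if (any(sys < 0) || any(stat < 0)) stop("uncertainties must be non-negative")
  sqrt(sys^2 + stat^2)
}

#' Mean and spread of a mixture distribution
#'
#' Two-moment formula for a finite mixture with component means \code{means},
#' standard deviations \code{sds} and weights \code{x}:
#' \eqn{\mu = \sum_j x_j \mu_j}, \eqn{\sigma^2 = \sum_j x_j(\sigma_j^2 +
#' \mu_j^2) - \mu^2}. Used for the zero-th order spread of the effective
#' parameters when a single voxelino is drawn from the component mixture.
#'
#' @param means component means
#' @param sds component standard deviations (>= 0)
#' @param x mixture weights (sum to 1)
#' @return list with \code{mean} and \code{sd}
#' @export
mixture_spread <- function(means, sds, x) {
  stopifnot(length(means) == length(sds), length(means) == length(x))
  if (any(sds < 0)) stop("sds must be non-negative")
  if (abs(sum(x) - 1) > 1e-9) stop("weights must sum to 1")
  mu <- sum(x * means)
  v <- sum(x * (sds^2 + means^2)) - mu^2
  list(mean = mu, sd = sqrt(max(v, 0)))
}

#' Central-limit shrinkage of the effective-parameter spread
#'
#' Averaging \code{Ns} independent voxelino draws shrinks the single-draw
#' spread \code{sd0} to \eqn{\Delta = \sigma_0/\sqrt{N_s}} (the standard
#' error of the mean), in line with the central limit theorem.
#'
#' @param sd0 single-voxelino standard deviation
#' @param Ns number of solute voxelinos per voxel (>= 1)
#' @return shrunk standard deviation
#' @export
delta_eff_single <- function(sd0, Ns) {
  if (any(Ns < 1)) stop("Ns must be >= 1")
  sd0 / sqrt(Ns)
}

#' Sensitivity of the effective parameters to the lipid volume fraction
#'
#' Closed-form partial derivatives of the binary effective PSV and RI
#' increment with respect to the relative lipid volume fraction
#' \code{x_lip}: from \eqn{\bar\theta_{\mathrm{eff}}(x) = (x/\theta_b +
#' (1-x)/\theta_a)^{-1}},
#' \deqn{\partial\bar\theta_{\mathrm{eff}}/\partial x =
#'   -\bar\theta_{\mathrm{eff}}^2 (1/\theta_b - 1/\theta_a),}
#' and the product rule applied to \eqn{\bar\alpha_{\mathrm{eff}} =
#' \bar\theta_{\mathrm{eff}}\,(x\,\alpha_b/\theta_b +
#' (1-x)\,\alpha_a/\theta_a)}.
#'
#' @param x_lip relative lipid volume fraction in \[0, 1\]
#' @param comp_a list with \code{alpha, theta} of the protein-like component
#' @param comp_b list with \code{alpha, theta} of the lipid component
#' @return list with \code{dtheta_dx} and \code{dalpha_dx} (mL/g per unit x)
#' @export
binary_partials <- function(x_lip, comp_a, comp_b) {
  if (any(x_lip < 0 | x_lip > 1)) stop("x_lip must lie in [0, 1]")
  th <- binary_effective_theta(x_lip, comp_a$theta, comp_b$theta)
  dth <- -th^2 * (1 / comp_b$theta - 1 / comp_a$theta)
  ra <- comp_a$alpha / comp_a$theta
  rb <- comp_b$alpha / comp_b$theta
  dal <- dth * (x_lip * rb + (1 - x_lip) * ra) + th * (rb - ra)
  list(dtheta_dx = dth, dalpha_dx = dal)
}

#' Voxel inhomogeneity parameters
#'
#' Collects the parameters that control voxel-to-voxel variability of a
#' binary (protein + lipid) solute: the mean and spread of the relative
#' lipid volume fraction, the mean solvent volume fraction, the relative
#' spread of the solute mass per voxel, the voxelino discretization and the
#' model for the number of solute voxelinos.
#'
#' @param x_lip_mean mean relative lipid volume fraction in \[0, 1\]
#' @param d_x_lip voxel-to-voxel SD of the lipid volume fraction (>= 0)
#' @param phi1_mean mean solvent volume fraction in \[0, 1\]
#' @param d_ms_rel relative SD of the solute mass per voxel (>= 0)
#' @param N0 voxelinos per voxel (integer >= 1)
#' @param ns_model \code{"binomial"} (equilibrium placement of solute
#'   voxelinos), \code{"mass_fluctuation"} (solute-mass bookkeeping,
#'   including composition-driven terms) or \code{"fixed"}
#' @return object of class \code{"inhomogeneity"}
#' @export
inhomogeneity <- function(x_lip_mean = 0, d_x_lip = 0, phi1_mean = 0.9,
                          d_ms_rel = 0, N0 = 1e4,
                          ns_model = c("mass_fluctuation", "binomial", "fixed")) {
  ns_model <- match.arg(ns_model)
  if (x_lip_mean < 0 || x_lip_mean > 1) stop("x_lip_mean must lie in [0, 1]")
  if (phi1_mean < 0 || phi1_mean > 1) stop("phi1_mean must lie in [0, 1]")
  if (d_x_lip < 0 || d_ms_rel < 0) stop("spreads must be non-negative")
  if (N0 < 1) stop("N0 must be >= 1")
  structure(list(x_lip_mean = x_lip_mean, d_x_lip = d_x_lip,
                 phi1_mean = phi1_mean, d_ms_rel = d_ms_rel, N0 = N0,
                 ns_model = ns_model),
            class = "inhomogeneity")
}

# single-voxelino mixture spreads of (theta, alpha) for a binary solute
.spread0 <- function(x_lip, a, b) {
  list(theta = mixture_spread(c(a$theta, b$theta),
                              c(a$dtheta %||% 0, b$dtheta %||% 0),
                              c(1 - x_lip, x_lip))$sd,
       alpha = mixture_spread(c(a$alpha, b$alpha),
                              c(a$dalpha %||% 0, b$dalpha %||% 0),
                              c(1 - x_lip, x_lip))$sd)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Total spread of the effective parameters
#'
#' Combines the central-limit shrinkage of the single-voxelino mixture
#' spread with the composition-fluctuation term:
#' \deqn{\Delta\theta_{\mathrm{eff}} = \sqrt{(\Delta\theta^0_{\mathrm{eff}}/
#'   \sqrt{N_s})^2 + (\partial\bar\theta_{\mathrm{eff}}/\partial\bar
#'   x_{lip}\,\Delta x_{lip})^2}} (and analogously for
#' \eqn{\Delta\alpha_{\mathrm{eff}}}), with \eqn{N_s = N_0(1 - \bar\phi_1)}.
#' For \eqn{\Delta x_{lip} > 0} the spreads plateau at the composition term
#' for large \eqn{N_0} instead of vanishing.
#'
#' @param params an [inhomogeneity()] object
#' @param comp_a,comp_b lists with \code{alpha, theta} and optional
#'   \code{dalpha, dtheta} for the two solute components
#' @return list with \code{d_theta_eff}, \code{d_alpha_eff} and a
#'   \code{components} breakdown (clt and composition terms)
#' @export
delta_eff_total <- function(params, comp_a, comp_b) {
  stopifnot(inherits(params, "inhomogeneity"))
  Ns <- params$N0 * (1 - params$phi1_mean)
  if (Ns < 1) stop("Ns = N0 (1 - phi1) must be >= 1")
  s0 <- .spread0(params$x_lip_mean, comp_a, comp_b)
  pd <- binary_partials(params$x_lip_mean, comp_a, comp_b)
  th_clt <- delta_eff_single(s0$theta, Ns)
  al_clt <- delta_eff_single(s0$alpha, Ns)
  th_x <- abs(pd$dtheta_dx) * params$d_x_lip
  al_x <- abs(pd$dalpha_dx) * params$d_x_lip
  list(d_theta_eff = sqrt(th_clt^2 + th_x^2),
       d_alpha_eff = sqrt(al_clt^2 + al_x^2),
       components = list(theta = c(clt = th_clt, composition = th_x),
                         alpha = c(clt = al_clt, composition = al_x)))
}

#' Spread of the solvent volume fraction
#'
#' The solvent volume fraction \eqn{\phi_1 = 1 - N_s/N_0} fluctuates with
#' the number of solute voxelinos. Under the \code{"binomial"} model
#' (\eqn{N_s \sim \mathrm{Bin}(N_0, 1 - \bar\phi_1)}) the spread is the
#' binomial proportion SD \eqn{\sqrt{\bar\phi_1 (1-\bar\phi_1)/N_0}}. Under
#' \code{"mass_fluctuation"} the solute-mass bookkeeping gives
#' \deqn{\Delta\phi_1 = (1 - \bar\phi_1)\sqrt{(\Delta\phi_1^0)^2 +
#'   (\Delta\phi_1^\infty)^2},}
#' with a central-limit component
#' \eqn{\Delta\phi_1^0 = \sqrt{[\bar\phi_1 +
#'   (\Delta\theta^0_{\mathrm{eff}}/\bar\theta_{\mathrm{eff}})^2] /
#'   [N_0 (1 - \bar\phi_1)]}}
#' and an inhomogeneity component
#' \eqn{\Delta\phi_1^\infty = \sqrt{(\Delta m_s/\bar m_s)^2 +
#'   (\partial\bar\theta_{\mathrm{eff}}/\partial\bar x_{lip}\,
#'    \Delta x_{lip}/\bar\theta_{\mathrm{eff}})^2}}
#' that survives at large \eqn{N_0}.
#'
#' @inheritParams delta_eff_total
#' @return list with \code{d_phi1} and a \code{components} breakdown
#' @export
delta_phi1 <- function(params, comp_a, comp_b) {
  stopifnot(inherits(params, "inhomogeneity"))
  p1 <- params$phi1_mean
  N0 <- params$N0
  if (params$ns_model == "fixed")
    return(list(d_phi1 = 0, components = c(clt = 0, inhomogeneity = 0)))
  if (params$ns_model == "binomial") {
    d <- sqrt(p1 * (1 - p1) / N0)
    return(list(d_phi1 = d, components = c(clt = d, inhomogeneity = 0)))
  }
  th_eff <- binary_effective_theta(params$x_lip_mean, comp_a$theta, comp_b$theta)
  s0 <- .spread0(params$x_lip_mean, comp_a, comp_b)
  pd <- binary_partials(params$x_lip_mean, comp_a, comp_b)
  d0 <- sqrt((p1 + (s0$theta / th_eff)^2) / (N0 * (1 - p1)))
  dinf <- sqrt(params$d_ms_rel^2 +
               (pd$dtheta_dx * params$d_x_lip / th_eff)^2)
  list(d_phi1 = (1 - p1) * sqrt(d0^2 + dinf^2),
       components = c(clt = (1 - p1) * d0, inhomogeneity = (1 - p1) * dinf))
}

#' Spread of the voxel refractive index
#'
#' Gaussian propagation through \eqn{n = n_1 + (1 - \phi_1)\,
#' \alpha_{\mathrm{eff}}/\theta_{\mathrm{eff}}} over
#' \eqn{\beta \in \{\alpha_{\mathrm{eff}}, \theta_{\mathrm{eff}}, \phi_1\}},
#' neglecting correlations:
#' \eqn{\partial n/\partial\phi_1 = -\alpha_{\mathrm{eff}}/
#' \theta_{\mathrm{eff}}},
#' \eqn{\partial n/\partial\alpha_{\mathrm{eff}} =
#' (1-\phi_1)/\theta_{\mathrm{eff}}},
#' \eqn{\partial n/\partial\theta_{\mathrm{eff}} = -(1-\phi_1)\,
#' \alpha_{\mathrm{eff}}/\theta_{\mathrm{eff}}^2}.
#'
#' @inheritParams delta_eff_total
#' @return list with \code{d_n} and a \code{components} breakdown
#' @export
delta_n <- function(params, comp_a, comp_b) {
  stopifnot(inherits(params, "inhomogeneity"))
  x <- params$x_lip_mean
  p1 <- params$phi1_mean
  th <- binary_effective_theta(x, comp_a$theta, comp_b$theta)
  y_lip <- mass_from_volume_weights(c(1 - x, x), c(comp_a$theta, comp_b$theta))[2]
  al <- (1 - y_lip) * comp_a$alpha + y_lip * comp_b$alpha
  de <- delta_eff_total(params, comp_a, comp_b)
  dp <- delta_phi1(params, comp_a, comp_b)
  terms <- c(phi1  = abs(-al / th) * dp$d_phi1,
             alpha = abs((1 - p1) / th) * de$d_alpha_eff,
             theta = abs(-(1 - p1) * al / th^2) * de$d_theta_eff)
  list(d_n = sqrt(sum(terms^2)), components = terms)
}

#' Spread of the voxel mass density
#'
#' Gaussian propagation through the density-RI mixture relation:
#' \deqn{\Delta\rho = \sqrt{\left(\frac{\bar\theta_{\mathrm{eff}}\rho_1 - 1}
#'   {\bar\theta_{\mathrm{eff}}}\,\Delta\phi_1\right)^2 +
#'   \left(\frac{\bar\phi_1 - 1}{\bar\theta_{\mathrm{eff}}^2}\,
#'   \Delta\theta_{\mathrm{eff}}\right)^2}.}
#' At the decoupling composition (\eqn{\bar\theta_{\mathrm{eff}} = 1/\rho_1})
#' the first term vanishes: the density becomes insensitive to solvent
#' fraction noise.
#'
#' @inheritParams delta_eff_total
#' @param solvent a [solvent()] object
#' @return list with \code{d_rho} and a \code{components} breakdown
#' @export
delta_rho <- function(params, comp_a, comp_b, solvent = ridens::solvent()) {
  stopifnot(inherits(params, "inhomogeneity"))
  th <- binary_effective_theta(params$x_lip_mean, comp_a$theta, comp_b$theta)
  de <- delta_eff_total(params, comp_a, comp_b)
  dp <- delta_phi1(params, comp_a, comp_b)
  terms <- c(phi1  = abs((th * solvent$rho1 - 1) / th) * dp$d_phi1,
             theta = abs((params$phi1_mean - 1) / th^2) * de$d_theta_eff)
  list(d_rho = sqrt(sum(terms^2)), components = terms)
}

#' Full closed-form uncertainty propagation
#'
#' Evaluates all propagated spreads (effective parameters, solvent volume
#' fraction, refractive index, mass density) for a binary solute, together
#' with the means they refer to. Each total equals the root-sum-square of
#' its component terms.
#'
#' @inheritParams delta_rho
#' @return object of class \code{"md_uncertainty"}
#' @export
propagate_uncertainty <- function(params, comp_a, comp_b, solvent = ridens::solvent()) {
  x <- params$x_lip_mean
  th <- binary_effective_theta(x, comp_a$theta, comp_b$theta)
  y_lip <- mass_from_volume_weights(c(1 - x, x), c(comp_a$theta, comp_b$theta))[2]
  al <- (1 - y_lip) * comp_a$alpha + y_lip * comp_b$alpha
  de <- delta_eff_total(params, comp_a, comp_b)
  dp <- delta_phi1(params, comp_a, comp_b)
  dn <- delta_n(params, comp_a, comp_b)
  dr <- delta_rho(params, comp_a, comp_b, solvent)
  p1 <- params$phi1_mean
  structure(list(
    mean = list(theta_eff = th, alpha_eff = al, phi1 = p1,
                n = solvent$n1 + (1 - p1) * al / th,
                rho = (1 - p1) / th + solvent$rho1 * p1),
    d_theta_eff = de$d_theta_eff, d_alpha_eff = de$d_alpha_eff,
    d_phi1 = dp$d_phi1, d_n = dn$d_n, d_rho = dr$d_rho,
    components = list(theta_eff = de$components$theta,
                      alpha_eff = de$components$alpha,
                      phi1 = dp$components, n = dn$components,
                      rho = dr$components),
    params = params), class = "md_uncertainty")
}

#' @export
print.md_uncertainty <- function(x, ...) {
  m <- x$mean
  cat("Closed-form uncertainty propagation (binary solute)\n")
  cat(sprintf("  means: theta_eff = %.4f, alpha_eff = %.4f mL/g, phi1 = %.3f\n",
              m$theta_eff, m$alpha_eff, m$phi1))
  cat(sprintf("         n = %.5f, rho = %.5f g/mL\n", m$n, m$rho))
  cat(sprintf("  spreads: d_theta_eff = %.3g, d_alpha_eff = %.3g mL/g\n",
              x$d_theta_eff, x$d_alpha_eff))
  cat(sprintf("           d_phi1 = %.3g, d_n = %.3g, d_rho = %.3g g/mL\n",
              x$d_phi1, x$d_n, x$d_rho))
  invisible(x)
}
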