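#' Mass density estimates from measured RI values
#'
#' Converts per-voxel RI measurements (e.g. exported from an ODT tomogram)
#' into mass-density estimates via the linear density-RI relation, with
#' Gaussian propagation of the parameter uncertainties
#' \eqn{(\Delta\alpha, \Delta\theta)} and of a per-measurement RI
#' uncertainty. Values below the solvent RI are flagged with a warning and
#' processed anyway (RI noise in real tomograms).
#'
#' @param ri measured refractive indices (one per voxel)
#' @param alpha RI increment, mL/g
#' @param theta PSV, mL/g
#' @param dalpha,dtheta standard deviations of \code{alpha}, \code{theta}
#' @param dn_sd standard deviation of the RI measurement (scalar or
#'   per-value); an asymmetric interval can be supplied as
#'   \code{c(lower, upper)} half-widths and is symmetrised to its mean
#' @param solvent a [solvent()] object
#' @return object of class \code{"md_estimate"}: data.frame with columns
#'   \code{ri, dn, rho, rho_sd}
#' @export
#' @examples
#' md_from_ri(1.3655, alpha = 0.1971, theta = 0.734,
#'            dalpha = 0.0033, dtheta = 0.009, dn_sd = c(0.0032, 0.0028))
md_from_ri <- function(ri, alpha, theta, dalpha = 0, dtheta = 0, dn_sd = 0,
                       solvent = ridens::solvent()) {
  stopifnot(is.numeric(ri))
  if (length(dn_sd) == 2L) dn_sd <- mean(dn_sd)
  dn <- ri - solvent$n1
  if (any(dn < 0)) warning(sprintf("%d RI value(s) below the solvent RI", sum(dn < 0)))
  rho <- suppressWarnings(rho_from_contrast(dn, alpha, theta, solvent$rho1))
  # partials of Eq.-9-type relation
  drho_ddn <- (1 - solvent$rho1 * theta) / alpha
  drho_dalpha <- -(dn / alpha^2) * (1 - solvent$rho1 * theta)
  drho_dtheta <- -solvent$rho1 * dn / alpha
  rho_sd <- sqrt((drho_ddn * dn_sd)^2 + (drho_dalpha * dalpha)^2 +
                 (drho_dtheta * dtheta)^2)
  out <- data.frame(ri = ri, dn = dn, rho = rho, rho_sd = rho_sd)
  attr(out, "params") <- list(alpha = alpha, theta = theta, dalpha = dalpha,
                              dtheta = dtheta, dn_sd = dn_sd, solvent = solvent)
  class(out) <- c("md_estimate", "data.frame")
  out
}

#' @export
print.md_estimate <- function(x, ...) {
  if (nrow(x) == 1L) {
    cat(sprintf("rho = %.4f +/- %.4f g/mL (at n = %.4f)\n",
                x$rho, x$rho_sd, x$ri))
  } else {
    cat(sprintf("Mass-density estimates for %d RI values\n", nrow(x)))
    m <- marginal_summary(x$rho)
    cat(sprintf("  median rho %.4f g/mL, 68%% CI [%.4f, %.4f]\n",
                m$median, m$ci68[1], m$ci68[2]))
  }
  invisible(x)
}

#' Predict the correlative density-RI distribution of a mixture
#'
#' End-to-end forward prediction: the closed-form density-RI line at the
#' mean composition, the effective parameters with their propagated
#' spreads (for binary solutes), and — when the specification carries
#' distributions — a Monte-Carlo voxel ensemble with marginal medians and
#' confidence intervals.
#'
#' @param spec a [mixture_spec()]
#' @param seed RNG seed for the MC ensemble
#' @param rule RI mixing rule for the ensemble
#' @param mc run the Monte-Carlo ensemble? (closed forms only if FALSE)
#' @return object of class \code{"md_prediction"} with elements
#'   \code{effective} (means), \code{line} (function \eqn{\rho(\delta n)}),
#'   \code{slope}, \code{uncertainty} (binary solutes only),
#'   \code{ensemble} and \code{summary} (if \code{mc})
#' @export
predict_density <- function(spec, seed = NULL, rule = "biot", mc = TRUE) {
  stopifnot(inherits(spec, "mixture_spec"))
  comp <- spec$composition
  sv <- comp$solvent
  eff <- composition_effective(comp)
  slope <- (1 - sv$rho1 * eff$theta_eff) / eff$alpha_eff
  line <- function(dn) rho_from_contrast(dn, eff$alpha_eff, eff$theta_eff, sv$rho1)
  unc <- NULL
  if (length(comp$x) == 2L) {
    params <- inhomogeneity(x_lip_mean = comp$x[2], d_x_lip = spec$x_sd,
                            phi1_mean = spec$phi1_mean, d_ms_rel = spec$dm_rel,
                            N0 = spec$N0,
                            ns_model = if (spec$ns_model == "fixed") "binomial" else spec$ns_model)
    ca <- list(alpha = comp$alpha[1], theta = comp$theta[1],
               dalpha = comp$dalpha[1], dtheta = comp$dtheta[1])
    cb <- list(alpha = comp$alpha[2], theta = comp$theta[2],
               dalpha = comp$dalpha[2], dtheta = comp$dtheta[2])
    unc <- propagate_uncertainty(params, ca, cb, sv)
  }
  ens <- NULL; smry <- NULL
  if (mc) {
    ens <- simulate_voxels(spec, seed = seed, rule = rule)
    smry <- summary(ens)
  }
  structure(list(effective = eff, line = line, slope = slope,
                 uncertainty = unc, ensemble = ens, summary = smry,
                 spec = spec, rule = rule),
            class = "md_prediction")
}

#' @export
print.md_prediction <- function(x, ...) {
  cat("Density-RI prediction\n")
  cat(sprintf("  alpha_eff = %.4f mL/g, theta_eff = %.4f mL/g, slope drho/dn = %.4f\n",
              x$effective$alpha_eff, x$effective$theta_eff, x$slope))
  if (!is.null(x$summary)) print(x$summary)
  invisible(x)
}
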