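#' Pycnometer volume calibration
#'
#' The pycnometer volume follows from weighing it filled with a liquid of
#' known density (distilled water): \eqn{v_{pyc} = (m_w - m_{pyc})/\rho_w}.
#'
#' @param m_w mass of the filled pycnometer, g
#' @param m_pyc mass of the empty pycnometer, g
#' @param rho_w density of the calibration liquid, g/mL
#' @return pycnometer volume, mL
#' @export
pycnometer_volume <- function(m_w, m_pyc, rho_w) {
  if (any(rho_w <= 0)) stop("calibration density must be positive")
  if (any(m_w <= m_pyc)) stop("filled mass must exceed the empty mass")
  (m_w - m_pyc) / rho_w
}

#' Liquid density from pycnometry
#'
#' \eqn{\rho = (m - m_{pyc})/v_{pyc}} for a sample weighed in a calibrated
#' pycnometer.
#'
#' @param m mass of the filled pycnometer, g
#' @param m_pyc mass of the empty pycnometer, g
#' @param v_pyc calibrated volume, mL
#' @return sample density, g/mL
#' @export
density_from_pycnometry <- function(m, m_pyc, v_pyc) {
  if (any(v_pyc <= 0)) stop("pycnometer volume must be positive")
  if (any(m < m_pyc)) stop("filled mass must not be below the empty mass")
  (m - m_pyc) / v_pyc
}

#' Solute concentration of a dilution
#'
#' For a stock of water mass fraction \code{y1_k}, a dilution made of
#' \code{m_k} g stock plus \code{m_wk} g added water has solute mass
#' fraction \eqn{y_s = m_k (1 - y_{1k})/(m_k + m_{wk})}; the concentration
#' is \eqn{c_s = y_s \rho_k} with the measured density \code{rho_k} of the
#' dilution.
#'
#' @param m_k stock mass in the dilution, g
#' @param m_wk added water mass, g
#' @param y1_k water mass fraction of the stock in \[0, 1\]
#' @param rho_k measured density of the dilution, g/mL
#' @return solute concentration, g/mL
#' @export
dilution_concentration <- function(m_k, m_wk, y1_k, rho_k) {
  if (any(m_k <= 0) || any(m_wk < 0)) stop("masses must be positive (stock) / non-negative (water)")
  if (any(y1_k < 0 | y1_k > 1)) stop("water mass fraction must lie in [0, 1]")
  ys <- m_k * (1 - y1_k) / (m_k + m_wk)
  ys * rho_k
}

#' Concentration series container
#'
#' Holds a refractometry/pycnometry dilution series: per-point solute
#' concentration, RI contrast and density with optional standard
#' deviations, referenced to a solvent.
#'
#' @param c solute concentrations, g/mL
#' @param dn RI contrasts (or NULL if not measured)
#' @param dn_sd per-point SDs of \code{dn} (NULL = unit weights)
#' @param rho densities, g/mL (or NULL)
#' @param rho_sd per-point SDs of \code{rho} (NULL = unit weights)
#' @param solvent a [solvent()] object
#' @param n_reps technical repetitions per point (bookkeeping only)
#' @return object of class \code{"concentration_series"}
#' @export
concentration_series <- function(c, dn = NULL, dn_sd = NULL, rho = NULL,
                                 rho_sd = NULL, solvent = ridens::solvent(),
                                 n_reps = 1L) {
  if (any(c < 0)) stop("concentrations must be non-negative")
  chk <- function(v, nm) {
    if (!is.null(v) && length(v) != length(c))
      stop(nm, " must match the length of c")
    v
  }
  if (!is.null(dn_sd) && any(dn_sd < 0)) stop("dn_sd must be >= 0")
  if (!is.null(rho_sd) && any(rho_sd < 0)) stop("rho_sd must be >= 0")
  structure(list(c = c, dn = chk(dn, "dn"), dn_sd = chk(dn_sd, "dn_sd"),
                 rho = chk(rho, "rho"), rho_sd = chk(rho_sd, "rho_sd"),
                 solvent = solvent, n_reps = n_reps),
            class = "concentration_series")
}

#' Read a concentration series from CSV
#'
#' Expects a header with columns \code{c}, and any of \code{dn, dn_sd,
#' rho, rho_sd}.
#'
#' @param path CSV file
#' @param solvent a [solvent()] object
#' @return a [concentration_series()]
#' @export
read_concentration_series <- function(path, solvent = ridens::solvent()) {
  d <- utils::read.csv(path)
  if (!"c" %in% names(d)) stop("CSV must have a 'c' column")
  concentration_series(d$c, dn = d$dn, dn_sd = d$dn_sd, rho = d$rho,
                       rho_sd = d$rho_sd, solvent = solvent)
}

# weighted regression of y on a single regressor through a fixed intercept;
# slope sd from the weighted normal equations. If sds are supplied the
# weights are 1/sd^2 and the slope variance is 1/sum(w x^2) (known-variance
# case); with unit weights the residual variance is estimated.
.wls_origin <- function(x, y, sd = NULL) {
  if (length(x) < 2L) stop("need at least 2 points to fit")
  if (all(x == 0)) stop("all concentrations are zero; slope is unidentified")
  known <- !is.null(sd) && any(sd > 0)
  w <- if (known) 1 / pmax(sd, 1e-12)^2 else rep(1, length(x))
  sxx <- sum(w * x^2)
  b <- sum(w * x * y) / sxx
  r <- y - b * x
  if (known) {
    vb <- 1 / sxx
  } else {
    s2 <- sum(r^2) / (length(x) - 1L)
    vb <- s2 / sum(x^2)
  }
  list(slope = b, sd = sqrt(vb), residuals = r,
       chi2 = sum(w * r^2), weights = w)
}

#' Fit the RI increment to a concentration series
#'
#' Weighted least squares of \eqn{\delta n = \alpha c} strictly through the
#' origin (the contrast vanishes at zero concentration by definition),
#' with inverse-variance weights from the per-point SDs when present.
#'
#' @param series a [concentration_series()] with \code{dn} data
#' @return list with \code{alpha_hat}, \code{sd}, \code{residuals},
#'   \code{chi2}
#' @export
fit_alpha <- function(series) {
  stopifnot(inherits(series, "concentration_series"))
  if (is.null(series$dn)) stop("series has no RI-contrast data")
  f <- .wls_origin(series$c, series$dn, series$dn_sd)
  list(alpha_hat = f$slope, sd = f$sd, residuals = f$residuals, chi2 = f$chi2)
}

#' Fit the PSV to a concentration series
#'
#' Weighted least squares of the density relation \eqn{\rho = \rho_1 +
#' (1 - \rho_1\theta)\,c}. By default the intercept is fixed at the known
#' solvent density (the solvent is treated as exact); \code{fix_intercept
#' = FALSE} frees it for diagnostics. The PSV follows from the slope as
#' \eqn{\hat\theta = (1 - b)/\rho_1} with its SD propagated from the slope
#' SD.
#'
#' @param series a [concentration_series()] with \code{rho} data
#' @param rho1 solvent density; defaults to the series solvent
#' @param fix_intercept fix the intercept at \code{rho1}?
#' @return list with \code{theta_hat}, \code{sd}, \code{slope},
#'   \code{residuals}, \code{chi2} (and \code{intercept} if freed)
#' @export
fit_theta <- function(series, rho1 = NULL, fix_intercept = TRUE) {
  stopifnot(inherits(series, "concentration_series"))
  if (is.null(series$rho)) stop("series has no density data")
  if (is.null(rho1)) rho1 <- series$solvent$rho1
  if (fix_intercept) {
    f <- .wls_origin(series$c, series$rho - rho1, series$rho_sd)
    b <- f$slope; vb <- f$sd^2
    out <- list(theta_hat = (1 - b) / rho1, sd = sqrt(vb) / rho1,
                slope = b, residuals = f$residuals, chi2 = f$chi2)
  } else {
    known <- !is.null(series$rho_sd) && any(series$rho_sd > 0)
    w <- if (known) 1 / pmax(series$rho_sd, 1e-12)^2 else rep(1, length(series$c))
    fit <- stats::lm(series$rho ~ series$c, weights = w)
    b <- stats::coef(fit)[2]
    vb <- stats::vcov(fit)[2, 2]
    if (known) {
      # known-variance case: rescale lm's dispersion estimate away
      s2 <- summary(fit)$sigma^2
      vb <- vb / s2
    }
    out <- list(theta_hat = unname((1 - b) / rho1), sd = sqrt(vb) / rho1,
                slope = unname(b), intercept = unname(stats::coef(fit)[1]),
                residuals = unname(stats::residuals(fit)),
                chi2 = sum(w * stats::residuals(fit)^2))
  }
  out
}

#' Fit a concentration series
#'
#' Joint interface to [fit_alpha()] and [fit_theta()] returning a classed
#' model object with the usual methods (\code{print}, \code{summary},
#' \code{coef}, \code{predict}, \code{residuals}). \code{predict} evaluates
#' the fitted density-RI line \eqn{\rho(\delta n)}.
#'
#' @param series a [concentration_series()]
#' @param fix_intercept passed to [fit_theta()]
#' @return object of class \code{"md_fit"}
#' @export
fit_series <- function(series, fix_intercept = TRUE) {
  stopifnot(inherits(series, "concentration_series"))
  fa <- if (!is.null(series$dn)) fit_alpha(series) else NULL
  ft <- if (!is.null(series$rho)) fit_theta(series, fix_intercept = fix_intercept) else NULL
  if (is.null(fa) && is.null(ft)) stop("series has neither dn nor rho data")
  structure(list(alpha = fa, theta = ft, series = series,
                 fix_intercept = fix_intercept),
            class = "md_fit")
}

#' @export
#' @method coef md_fit
coef.md_fit <- function(object, ...) {
  c(alpha = if (!is.null(object$alpha)) object$alpha$alpha_hat else NA_real_,
    theta = if (!is.null(object$theta)) object$theta$theta_hat else NA_real_)
}

#' @export
print.md_fit <- function(x, ...) {
  cat("Concentration-series fit\n")
  if (!is.null(x$alpha))
    cat(sprintf("  alpha = %.4f +/- %.4f mL/g (chi2 = %.3g)\n",
                x$alpha$alpha_hat, x$alpha$sd, x$alpha$chi2))
  if (!is.null(x$theta))
    cat(sprintf("  theta = %.4f +/- %.4f mL/g (chi2 = %.3g)\n",
                x$theta$theta_hat, x$theta$sd, x$theta$chi2))
  invisible(x)
}

#' @export
#' @method summary md_fit
summary.md_fit <- function(object, ...) {
  print(object)
  sv <- object$series$solvent
  if (!is.null(object$alpha) && !is.null(object$theta)) {
    sl <- (1 - sv$rho1 * object$theta$theta_hat) / object$alpha$alpha_hat
    cat(sprintf("  implied density-RI slope drho/dn = %.4f (g/mL per RI unit)\n", sl))
  }
  invisible(object)
}

#' @export
predict.md_fit <- function(object, dn, ...) {
  if (is.null(object$alpha) || is.null(object$theta))
    stop("predicting rho(dn) needs both alpha and theta fits")
  sv <- object$series$solvent
  rho_from_contrast(dn, object$alpha$alpha_hat, object$theta$theta_hat, sv$rho1)
}

#' @export
#' @method residuals md_fit
residuals.md_fit <- function(object, which = c("dn", "rho"), ...) {
  which <- match.arg(which)
  if (which == "dn") object$alpha$residuals else object$theta$residuals
}

#' Compare RI mixing rules against a fitted series
#'
#' For each mixing rule, the solute RI implied by the fitted
#' \eqn{(\hat\alpha, \hat\theta)} (inverting the rule's dilute-limit RI
#' increment) is compared with the solute RI predicted from the known
#' chemical composition. Rules are ranked by absolute discrepancy;
#' inversion failures are flagged per rule rather than aborting.
#'
#' @param fit an [fit_series()] result with both parameters
#' @param comp a [solute_composition()] describing the known composition
#' @return data.frame with columns \code{rule, n2_implied, n2_predicted,
#'   discrepancy}, ranked best-first
#' @export
compare_mixing_rules <- function(fit, comp) {
  stopifnot(inherits(fit, "md_fit"), inherits(comp, "solute_composition"))
  if (is.null(fit$alpha) || is.null(fit$theta))
    stop("need both alpha and theta fits")
  a <- fit$alpha$alpha_hat; th <- fit$theta$theta_hat
  sv <- comp$solvent; n1 <- sv$n1
  implied <- list(
    biot = function() n1 + a / th,
    lorentz_lorenz = function() {
      # alpha_LL(c->0) = theta (L(n2) - L(n1)) / L'(n1)
      Lp1 <- 6 * n1 / (n1^2 + 2)^2
      n_of_ll(ll_of_n(n1) + a * Lp1 / th)
    },
    wiener = function() {
      k <- 2 * a / (3 * th * n1)
      if (k >= 1) stop("no real Wiener solution")
      sqrt(n1^2 * (1 + 2 * k) / (1 - k))
    })
  predicted <- list(
    biot = function() sum(comp$x * comp$n),
    lorentz_lorenz = function() n_of_ll(sum(comp$x * ll_of_n(comp$n))),
    wiener = function() n_of_ll(sum(comp$x * ll_of_n(comp$n))))
  rows <- lapply(names(implied), function(r) {
    ni <- tryCatch(implied[[r]](), error = function(e) NA_real_)
    np <- tryCatch(predicted[[r]](), error = function(e) NA_real_)
    data.frame(rule = r, n2_implied = ni, n2_predicted = np,
               discrepancy = abs(ni - np), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$discrepancy), ]
}

#' Generate a synthetic concentration series
#'
#' Fixture generator emulating a refractometry/pycnometry dilution
#' experiment: RI contrasts and densities follow the linear mixture
#' relations for the supplied \code{(alpha, theta)} with independent
#' Gaussian noise added.
#'
#' @param alpha generating RI increment, mL/g
#' @param theta generating PSV, mL/g
#' @param rho1 solvent density, g/mL
#' @param c_grid concentrations, g/mL
#' @param noise_dn SD of the RI-contrast noise (0 = exact)
#' @param noise_rho SD of the density noise, g/mL
#' @param seed RNG seed
#' @return a [concentration_series()] with per-point SDs set to the noise
#'   levels
#' @export
generate_synthetic_series <- function(alpha, theta, rho1 = 0.997,
                                      c_grid = seq(0.01, 0.08, length.out = 8),
                                      noise_dn = 0, noise_rho = 0, seed = 1L) {
  if (noise_dn < 0 || noise_rho < 0) stop("noise levels must be >= 0")
  if (any(c_grid * theta > 1)) stop("c_grid exceeds the packing limit 1/theta")
  set.seed(seed)
  dn <- contrast_from_concentration(c_grid, alpha) +
    stats::rnorm(length(c_grid), 0, noise_dn)
  rho <- rho_from_concentration(c_grid, theta, rho1) +
    stats::rnorm(length(c_grid), 0, noise_rho)
  concentration_series(c_grid, dn = dn,
                       dn_sd = if (noise_dn > 0) rep(noise_dn, length(c_grid)) else NULL,
                       rho = rho,
                       rho_sd = if (noise_rho > 0) rep(noise_rho, length(c_grid)) else NULL,
                       solvent = solvent(rho1 = rho1))
}
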