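#' Truncated-normal sampling on an interval
#'
#' Inverse-CDF sampling of a normal distribution truncated to
#' \code{[lo, hi]} (volume fractions use \code{[0, 1]}). With
#' \code{sigma = 0} the constant \code{mu} (clipped to the interval) is
#' returned. If the acceptance mass of the interval is vanishingly small
#' the parameters are rejected.
#'
#' @param n number of samples
#' @param mu mean of the parent normal
#' @param sigma standard deviation of the parent normal (>= 0)
#' @param lo,hi truncation bounds, \code{lo < hi}
#' @return \code{n} samples in \code{[lo, hi]}
#' @export
sample_truncated_normal <- function(n, mu, sigma, lo = 0, hi = 1) {
  stopifnot(lo < hi, sigma >= 0)
  if (sigma == 0) return(rep(min(max(mu, lo), hi), n))
  plo <- stats::pnorm(lo, mu, sigma)
  phi <- stats::pnorm(hi, mu, sigma)
  if (phi - plo < 1e-12)
    stop("truncation interval carries negligible probability mass for (mu, sigma)")
  stats::qnorm(stats::runif(n, plo, phi), mu, sigma)
}

#' Mixture specification for the voxel Monte-Carlo simulator
#'
#' Describes a sample as a solvent plus a multi-component solute with
#' per-voxel stochasticity: the solvent volume fraction and (for binary
#' solutes) the relative lipid volume fraction follow normal distributions
#' truncated to \[0, 1\]; the number of solute voxelinos per voxel follows
#' the chosen \code{ns_model}; per-voxelino RI increments and PSVs are
#' drawn from the component distributions.
#'
#' @param composition a [solute_composition()]; its \code{x} are the mean
#'   relative volume fractions
#' @param phi1_mean,phi1_sd truncated-normal parameters of the solvent
#'   volume fraction
#' @param x_sd voxel-to-voxel SD of the last component's relative volume
#'   fraction (binary solutes only; 0 = fixed composition)
#' @param N0 voxelinos per voxel
#' @param Nv number of voxels to simulate
#' @param ns_model \code{"binomial"}, \code{"mass_fluctuation"} or
#'   \code{"fixed"}; see [inhomogeneity()]
#' @param dm_rel relative SD of the solute mass per voxel (used by
#'   \code{"mass_fluctuation"})
#' @param seed default RNG seed stored with the spec
#' @return object of class \code{"mixture_spec"}
#' @export
mixture_spec <- function(composition, phi1_mean, phi1_sd = 0, x_sd = 0,
                         N0 = 1e4, Nv = 1000,
                         ns_model = c("binomial", "mass_fluctuation", "fixed"),
                         dm_rel = 0, seed = 1L) {
  ns_model <- match.arg(ns_model)
  stopifnot(inherits(composition, "solute_composition"))
  if (phi1_mean < 0 || phi1_mean > 1) stop("phi1_mean must lie in [0, 1]")
  if (phi1_sd < 0 || x_sd < 0 || dm_rel < 0) stop("spreads must be non-negative")
  if (x_sd > 0 && length(composition$x) != 2L)
    stop("x_sd > 0 is only supported for binary solutes")
  if (N0 < 1 || Nv < 1) stop("N0 and Nv must be >= 1")
  structure(list(composition = composition, phi1_mean = phi1_mean,
                 phi1_sd = phi1_sd, x_sd = x_sd, N0 = as.integer(round(N0)),
                 Nv = as.integer(round(Nv)), ns_model = ns_model,
                 dm_rel = dm_rel, seed = seed),
            class = "mixture_spec")
}

#' Read a mixture specification from YAML
#'
#' The file holds a \code{solvent} mapping (\code{n1, rho1}), a
#' \code{components} mapping (each entry with \code{x} and either
#' \code{alpha/theta} or \code{n/rho}, plus optional \code{dalpha/dtheta}),
#' and top-level \code{phi1_mean, phi1_sd, x_sd, N0, Nv, ns_model, dm_rel,
#' seed}. See the bundled zebrafish trunk configuration at
#' \code{system.file("extdata", "zebrafish_trunk.yaml", package = "ridens")}.
#'
#' @param path YAML file
#' @return a [mixture_spec()]
#' @export
read_mixture_spec <- function(path) {
  cfg <- yaml::read_yaml(path)
  sv <- if (is.null(cfg$solvent)) solvent() else
    solvent(cfg$solvent$n1 %||% 1.3330, cfg$solvent$rho1 %||% 0.997)
  if (is.null(cfg$components) || length(cfg$components) == 0L)
    stop("mixture spec must list at least one solute component")
  comps <- lapply(names(cfg$components), function(nm) {
    e <- .fix_yaml_n(cfg$components[[nm]])
    if (!is.null(e$n) && !is.null(e$rho))
      material(nm, n = e$n, rho = e$rho,
               dR = e$dR %||% 0, dtheta = e$dtheta %||% 0)
    else
      list(name = nm, alpha = e$alpha, theta = e$theta,
           dalpha = e$dalpha %||% 0, dtheta = e$dtheta %||% 0)
  })
  x <- vapply(cfg$components, function(e) e$x, numeric(1))
  comp <- solute_composition(comps, unname(x), sv)
  mixture_spec(comp,
               phi1_mean = cfg$phi1_mean, phi1_sd = cfg$phi1_sd %||% 0,
               x_sd = cfg$x_sd %||% 0, N0 = cfg$N0 %||% 1e4,
               Nv = cfg$Nv %||% 1000,
               ns_model = cfg$ns_model %||% "binomial",
               dm_rel = cfg$dm_rel %||% 0, seed = cfg$seed %||% 1L)
}

#' @export
print.mixture_spec <- function(x, ...) {
  cat("Voxel Monte-Carlo mixture specification\n")
  print(x$composition)
  cat(sprintf("  phi1 ~ T(%.3f, %.3f) on [0,1]; x fluctuation sd = %.3f\n",
              x$phi1_mean, x$phi1_sd, x$x_sd))
  cat(sprintf("  N0 = %d voxelinos/voxel, Nv = %d voxels, ns_model = %s, dm_rel = %.3g\n",
              x$N0, x$Nv, x$ns_model, x$dm_rel))
  invisible(x)
}

# Draw per-component voxelino sums for one component across all voxels.
# Exact path: individual normal draws (theta guarded positive).
# Fast path (large counts): the per-voxelino deviations are summed
# analytically -- Gaussian sums with moments matched to the component
# distribution (central-limit equivalent).
.component_sums <- function(Nj, comp_j, n1, need_ll, exact_threshold = 2000L) {
  Nv <- length(Nj)
  out <- list(S1 = numeric(Nv), S2 = numeric(Nv), SL = numeric(Nv))
  th <- comp_j$theta; al <- comp_j$alpha
  dth <- comp_j$dtheta; dal <- comp_j$dalpha
  if (max(Nj) <= exact_threshold) {
    tot <- sum(Nj)
    if (tot == 0L) return(out)
    idx <- rep.int(seq_len(Nv), Nj)
    thetai <- stats::rnorm(tot, th, dth)
    tries <- 0L
    while (any(bad <- thetai <= 0)) {
      tries <- tries + 1L
      if (tries > 100L) stop("could not draw positive PSV values; check dtheta")
      thetai[bad] <- stats::rnorm(sum(bad), th, dth)
    }
    alphai <- stats::rnorm(tot, al, dal)
    acc <- function(v) {
      s <- numeric(Nv)
      r <- rowsum(v, idx)
      s[as.integer(rownames(r))] <- r[, 1L]
      s
    }
    out$S1 <- acc(1 / thetai)
    out$S2 <- acc(alphai / thetai)
    if (need_ll) out$SL <- acc(ll_of_n(n1 + alphai / thetai))
  } else {
    # second-order means, first-order (delta-method) fluctuations
    rth2 <- (dth / th)^2
    m1 <- (1 / th) * (1 + rth2)
    m2 <- (al / th) * (1 + rth2)
    sq <- sqrt(Nj)
    Sth <- stats::rnorm(Nv, 0, 1) * sq * dth
    Sal <- stats::rnorm(Nv, 0, 1) * sq * dal
    out$S1 <- Nj * m1 - Sth / th^2
    out$S2 <- Nj * m2 + Sal / th - al * Sth / th^2
    if (need_ll) {
      nbar <- n1 + al / th
      var_n <- dal^2 / th^2 + al^2 * dth^2 / th^4
      Lp <- 6 * nbar / (nbar^2 + 2)^2
      Lpp <- 6 * (2 - 3 * nbar^2) / (nbar^2 + 2)^3
      out$SL <- Nj * (ll_of_n(nbar) + 0.5 * Lpp * var_n) + Lp * (out$S2 - Nj * m2)
    }
  }
  out
}

#' Simulate a voxel ensemble
#'
#' Runs the voxel/voxelino Monte-Carlo: for each of \code{Nv} voxels draws
#' the solvent volume fraction, the solute composition, the number of
#' solute voxelinos, and per-voxelino (RI increment, PSV) values; computes
#' the voxel mass density (mass balance over voxelinos) and refractive
#' index (Biot volume average over voxelinos, or the Lorentz-Lorenz mixing
#' rule). Components with large voxelino counts use a distributionally
#' equivalent Gaussian-sum fast path so that \code{N0 = 1e5} ensembles run
#' in seconds; the exact per-voxelino path is used for small counts and
#' serves as its oracle.
#'
#' Reproducible bit-for-bit for a given \code{(spec, seed)}.
#'
#' @param spec a [mixture_spec()]
#' @param seed RNG seed; defaults to the seed stored in the spec
#' @param rule RI mixing rule: \code{"biot"} or \code{"lorentz_lorenz"}
#' @param exact force the exact per-voxelino path regardless of counts
#' @return object of class \code{"voxel_ensemble"}: a data.frame with one
#'   row per voxel and columns \code{rho, n, dn, phi1, x_lip, Ns,
#'   alpha_eff, theta_eff}
#' @export
simulate_voxels <- function(spec, seed = NULL, rule = c("biot", "lorentz_lorenz"),
                            exact = FALSE) {
  rule <- match.arg(rule)
  stopifnot(inherits(spec, "mixture_spec"))
  set.seed(if (is.null(seed)) spec$seed else seed)
  comp <- spec$composition
  sv <- comp$solvent
  Nv <- spec$Nv; N0 <- spec$N0
  k <- length(comp$x)

  phi1 <- sample_truncated_normal(Nv, spec$phi1_mean, spec$phi1_sd)

  # per-voxel component weights
  if (spec$x_sd > 0) {
    x2 <- sample_truncated_normal(Nv, comp$x[2], spec$x_sd)
    xw <- cbind(1 - x2, x2)
  } else {
    xw <- matrix(comp$x, nrow = Nv, ncol = k, byrow = TRUE)
    x2 <- if (k >= 2) xw[, k] else rep(0, Nv)
  }

  Ns <- switch(spec$ns_model,
    fixed = as.integer(round(N0 * (1 - phi1))),
    binomial = stats::rbinom(Nv, N0, 1 - phi1),
    mass_fluctuation = {
      base <- stats::rbinom(Nv, N0, 1 - phi1)
      eps <- stats::rnorm(Nv, 0, spec$dm_rel)
      pmin.int(pmax.int(as.integer(round(base * (1 + eps))), 0L), N0)
    })

  # multinomial split of Ns over components (sequential binomials)
  counts <- matrix(0L, Nv, k)
  rem <- Ns
  prem <- rep(1, Nv)
  for (j in seq_len(k)) {
    if (j == k) { counts[, j] <- rem; break }
    pj <- pmin(pmax(xw[, j] / prem, 0), 1)
    counts[, j] <- stats::rbinom(Nv, rem, pj)
    rem <- rem - counts[, j]
    prem <- prem - xw[, j]
  }

  need_ll <- rule == "lorentz_lorenz"
  thr <- if (exact) .Machine$integer.max else 2000L
  S1 <- numeric(Nv); S2 <- numeric(Nv); SL <- numeric(Nv)
  for (j in seq_len(k)) {
    cj <- list(alpha = comp$alpha[j], theta = comp$theta[j],
               dalpha = comp$dalpha[j], dtheta = comp$dtheta[j])
    s <- .component_sums(counts[, j], cj, sv$n1, need_ll, thr)
    S1 <- S1 + s$S1; S2 <- S2 + s$S2; SL <- SL + s$SL
  }

  phi1_real <- 1 - Ns / N0
  rho <- phi1_real * sv$rho1 + S1 / N0
  if (need_ll) {
    Lmix <- phi1_real * ll_of_n(sv$n1) + SL / N0
    n <- n_of_ll(Lmix)
  } else {
    n <- sv$n1 + S2 / N0
  }
  dn <- n - sv$n1
  theta_eff <- ifelse(Ns > 0, Ns / S1, NA_real_)
  alpha_eff <- ifelse(Ns > 0, S2 / S1, NA_real_)

  out <- data.frame(rho = rho, n = n, dn = dn, phi1 = phi1_real,
                    x_lip = x2, Ns = Ns,
                    alpha_eff = alpha_eff, theta_eff = theta_eff)
  attr(out, "spec") <- spec
  attr(out, "rule") <- rule
  attr(out, "seed") <- if (is.null(seed)) spec$seed else seed
  class(out) <- c("voxel_ensemble", "data.frame")
  out
}

#' Draw a single voxel
#'
#' Convenience wrapper equivalent to [simulate_voxels()] with
#' \code{Nv = 1}: returns the (density, RI) pair of one voxel together with
#' the latent draws.
#'
#' @inheritParams simulate_voxels
#' @return a one-row \code{voxel_ensemble}
#' @export
sample_voxel <- function(spec, seed = NULL, rule = "biot", exact = FALSE) {
  spec$Nv <- 1L
  simulate_voxels(spec, seed = seed, rule = rule, exact = exact)
}

#' Median and central confidence intervals of a sample
#'
#' Marginal summary used for ensemble distributions: the median plus the
#' central 68\% (15.865/84.135 percentiles) and 95\% (2.275/97.725
#' percentiles) intervals.
#'
#' @param samples numeric vector with at least 10 values
#' @return list with \code{median}, \code{ci68 = c(lo, hi)},
#'   \code{ci95 = c(lo, hi)}
#' @export
marginal_summary <- function(samples) {
  samples <- samples[is.finite(samples)]
  if (length(samples) < 10L) stop("need at least 10 samples for a marginal summary")
  q <- stats::quantile(samples,
                       c(0.02275, 0.15865, 0.5, 0.84135, 0.97725),
                       names = FALSE)
  list(median = q[3], ci68 = c(q[2], q[4]), ci95 = c(q[1], q[5]))
}

#' @export
#' @method summary voxel_ensemble
summary.voxel_ensemble <- function(object, ...) {
  s <- list(rho = marginal_summary(object$rho),
            n = marginal_summary(object$n),
            dn = marginal_summary(object$dn))
  class(s) <- "voxel_ensemble_summary"
  s
}

#' @export
print.voxel_ensemble_summary <- function(x, ...) {
  fmt <- function(nm, m)
    cat(sprintf("  %-4s median %.5f  68%% CI [%.5f, %.5f]  95%% CI [%.5f, %.5f]\n",
                nm, m$median, m$ci68[1], m$ci68[2], m$ci95[1], m$ci95[2]))
  cat("Voxel ensemble marginals:\n")
  fmt("rho", x$rho); fmt("n", x$n); fmt("dn", x$dn)
  invisible(x)
}

#' @export
print.voxel_ensemble <- function(x, ...) {
  spec <- attr(x, "spec")
  cat(sprintf("Voxel ensemble: %d voxels (N0 = %d, rule = %s, seed = %s)\n",
              nrow(x), spec$N0, attr(x, "rule"), format(attr(x, "seed"))))
  print(summary(x))
  invisible(x)
}

#' Mass-calibrated confidence contours of a bivariate sample
#'
#' Estimates the joint density of paired samples by a 2-D Gaussian kernel
#' density estimate (Scott bandwidth, 256 x 256 grid by default) and picks
#' iso-density thresholds such that the enclosed probability mass of the
#' KDE equals each requested level, returning closed contour polylines.
#'
#' @param x,y paired samples (at least 100 pairs)
#' @param levels probability masses for the contours
#' @param n_grid grid resolution per axis
#' @return object of class \code{"density_contours"}: list with the KDE
#'   \code{grid}, per-level density \code{thresholds} and \code{polylines}
#'   (data.frames with columns x, y, level)
#' @export
confidence_contours <- function(x, y, levels = c(0.68, 0.95), n_grid = 256L) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 100L) stop("need at least 100 paired samples")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate (zero-variance) axis; use marginal_summary() instead")
  # Scott bandwidth per axis; kde2d's h is 4x the kernel sd
  bw <- function(v) stats::sd(v) * length(v)^(-1 / 6)
  kd <- MASS::kde2d(x, y, h = c(4 * bw(x), 4 * bw(y)), n = n_grid)
  cell <- diff(kd$x[1:2]) * diff(kd$y[1:2])
  dens <- sort(as.vector(kd$z), decreasing = TRUE)
  cum <- cumsum(dens) * cell
  thresholds <- vapply(levels, function(l) {
    i <- which(cum >= l)[1]
    if (is.na(i)) min(dens) else dens[i]
  }, numeric(1))
  polylines <- do.call(rbind, lapply(seq_along(levels), function(i) {
    cl <- grDevices::contourLines(kd$x, kd$y, kd$z, levels = thresholds[i])
    if (length(cl) == 0L) return(NULL)
    do.call(rbind, lapply(seq_along(cl), function(s)
      data.frame(x = cl[[s]]$x, y = cl[[s]]$y, level = levels[i],
                 segment = sprintf("%d.%d", i, s))))
  }))
  structure(list(grid = kd, thresholds = thresholds, levels = levels,
                 polylines = polylines),
            class = "density_contours")
}

#' Empirical mass enclosed by density contours
#'
#' Fraction of the paired samples whose (bilinearly interpolated) KDE
#' density lies at or above each contour threshold — a self-consistency
#' check that the contours enclose their nominal probability mass.
#'
#' @param contours a [confidence_contours()] object
#' @param x,y paired samples to evaluate (typically those used for the KDE)
#' @return named numeric vector of enclosed fractions, one per level
#' @export
enclosed_mass <- function(contours, x, y) {
  kd <- contours$grid
  fx <- findInterval(x, kd$x, all.inside = TRUE)
  fy <- findInterval(y, kd$y, all.inside = TRUE)
  tx <- (x - kd$x[fx]) / diff(kd$x[1:2])
  ty <- (y - kd$y[fy]) / diff(kd$y[1:2])
  tx <- pmin(pmax(tx, 0), 1); ty <- pmin(pmax(ty, 0), 1)
  z <- kd$z
  d <- z[cbind(fx, fy)] * (1 - tx) * (1 - ty) +
       z[cbind(fx + 1L, fy)] * tx * (1 - ty) +
       z[cbind(fx, fy + 1L)] * (1 - tx) * ty +
       z[cbind(fx + 1L, fy + 1L)] * tx * ty
  out <- vapply(contours$thresholds, function(th) mean(d >= th), numeric(1))
  names(out) <- paste0(100 * contours$levels, "%")
  out
}

#' @export
#' @method plot voxel_ensemble
plot.voxel_ensemble <- function(x, ...) {
  cc <- confidence_contours(x$dn, x$rho)
  graphics::plot(x$dn, x$rho, pch = ".", col = "grey40",
                 xlab = expression(delta * n), ylab = expression(rho ~ "(g/mL)"),
                 ...)
  for (g in split(cc$polylines, cc$polylines$segment))
    graphics::lines(g$x, g$y, lty = if (g$level[1] < 0.9) 1 else 2)
  invisible(x)
}
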