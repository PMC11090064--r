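test_that("systematic and statistical uncertainties combine in quadrature", {
  expect_equal(combine_uncertainties(0, 2), 2)
  expect_equal(combine_uncertainties(3, 4), 5)
  expect_equal(combine_uncertainties(4, 3), combine_uncertainties(3, 4))
  expect_error(combine_uncertainties(-1, 2), "non-negative")
})

test_that("mixture spread follows the two-moment formula", {
  one <- mixture_spread(0.7, 0.01, 1)
  expect_equal(one$mean, 0.7)
  expect_equal(one$sd, 0.01)
  # two delta components: Bernoulli spread |mu1 - mu2|/2 at x = 0.5
  two <- mixture_spread(c(0.734, 1.1016), c(0, 0), c(0.5, 0.5))
  expect_equal(two$sd, (1.1016 - 0.734) / 2)
  # spread is maximized at x = 0.5
  xs <- seq(0.05, 0.95, by = 0.05)
  sds <- vapply(xs, function(x)
    mixture_spread(c(0.7, 1.1), c(0.01, 0.01), c(1 - x, x))$sd, numeric(1))
  expect_equal(xs[which.max(sds)], 0.5)
})

test_that("central-limit shrinkage matches a Monte-Carlo oracle", {
  expect_equal(delta_eff_single(0.3, 1), 0.3)
  expect_equal(delta_eff_single(0.009, 81), 0.001)
  # MC oracle: sd of the mean of Ns iid draws
  set.seed(3)
  Ns <- 25
  means <- replicate(1e4, mean(rnorm(Ns, 0.734, 0.012)))
  expect_equal(sd(means), delta_eff_single(0.012, Ns), tolerance = 0.05)
})

test_that("binary partial derivatives agree with central finite differences", {
  a <- protein_comp(); b <- triolein_comp()
  h <- 1e-6
  for (x in c(0.1, 0.3, 0.5, 0.8)) {
    pd <- binary_partials(x, a, b)
    fd_th <- (binary_effective_theta(x + h, a$theta, b$theta) -
              binary_effective_theta(x - h, a$theta, b$theta)) / (2 * h)
    expect_equal(pd$dtheta_dx, fd_th, tolerance = 1e-6)
    al_of_x <- function(xx) {
      y <- mass_from_volume_weights(c(1 - xx, xx), c(a$theta, b$theta))
      sum(y * c(a$alpha, b$alpha))
    }
    fd_al <- (al_of_x(x + h) - al_of_x(x - h)) / (2 * h)
    expect_equal(pd$dalpha_dx, fd_al, tolerance = 1e-6)
  }
  same <- list(alpha = 0.2, theta = 0.7)
  expect_equal(binary_partials(0.4, same, same)$dtheta_dx, 0)
  # theta_b > theta_a makes the effective PSV increase with x
  expect_gt(binary_partials(0.5, a, b)$dtheta_dx, 0)
})

test_that("effective-parameter spread reduces, plateaus and decomposes correctly", {
  a <- protein_comp(); b <- triolein_comp()
  # no composition fluctuation: pure central-limit term
  p0 <- inhomogeneity(0.5, 0, 0.9, 0, 1e4, "mass_fluctuation")
  de <- delta_eff_total(p0, a, b)
  Ns <- 1e4 * 0.1
  s0 <- mixture_spread(c(a$theta, b$theta), c(a$dtheta, b$dtheta), c(0.5, 0.5))$sd
  expect_equal(de$d_theta_eff, s0 / sqrt(Ns), tolerance = 1e-12)
  # composition fluctuation: plateau at |partial| * dx for large N0
  px <- inhomogeneity(0.5, 0.1, 0.9, 0, 1e12, "mass_fluctuation")
  dex <- delta_eff_total(px, a, b)
  pd <- binary_partials(0.5, a, b)
  expect_equal(dex$d_theta_eff, abs(pd$dtheta_dx) * 0.1, tolerance = 1e-4)
  expect_equal(dex$d_alpha_eff, abs(pd$dalpha_dx) * 0.1, tolerance = 1e-4)
  # components recombine to the total in quadrature
  pm <- inhomogeneity(0.5, 0.1, 0.9, 0, 1e4, "mass_fluctuation")
  dm <- delta_eff_total(pm, a, b)
  expect_equal(dm$d_theta_eff, sqrt(sum(dm$components$theta^2)), tolerance = 1e-12)
  expect_equal(dm$d_alpha_eff, sqrt(sum(dm$components$alpha^2)), tolerance = 1e-12)
})

test_that("solvent-fraction spread has binomial, mass and composition limits", {
  a <- protein_comp(); b <- triolein_comp()
  # binomial model reduces to the binomial proportion SD
  pb <- inhomogeneity(0.5, 0, 0.9, 0, 1e4, "binomial")
  expect_equal(delta_phi1(pb, a, b)$d_phi1, sqrt(0.9 * 0.1 / 1e4),
               tolerance = 1e-12)
  # mass-fluctuation model with no component spread: sqrt(phi1 (1-phi1)/N0)
  a0 <- list(alpha = 0.197, theta = 0.734, dalpha = 0, dtheta = 0)
  p0 <- inhomogeneity(0, 0, 0.9, 0, 1e4, "mass_fluctuation")
  expect_equal(delta_phi1(p0, a0, a0)$d_phi1, sqrt(0.9 * 0.1 / 1e4),
               tolerance = 1e-12)
  # homogeneous limit vanishes
  pinf <- inhomogeneity(0, 0, 0.9, 0, 1e14, "mass_fluctuation")
  expect_lt(delta_phi1(pinf, a0, a0)$d_phi1, 1e-6)
  # pure solute-mass fluctuation at large N0: (1 - phi1) * dms
  pm <- inhomogeneity(0, 0, 0.9, 0.05, 1e14, "mass_fluctuation")
  expect_equal(delta_phi1(pm, a0, a0)$d_phi1, 0.1 * 0.05, tolerance = 1e-4)
  expect_equal(delta_phi1(inhomogeneity(0, 0, 0.9, 0, 10, "fixed"), a, b)$d_phi1, 0)
})

test_that("RI spread partials agree with finite differences of the mixture RI", {
  a <- protein_comp(); b <- triolein_comp()
  x <- 0.4; p1 <- 0.88
  y <- mass_from_volume_weights(c(1 - x, x), c(a$theta, b$theta))
  al <- sum(y * c(a$alpha, b$alpha))
  th <- binary_effective_theta(x, a$theta, b$theta)
  n_of <- function(alpha, theta, phi1) 1.3330 + (1 - phi1) * alpha / theta
  h <- 1e-7
  expect_equal((n_of(al + h, th, p1) - n_of(al - h, th, p1)) / (2 * h),
               (1 - p1) / th, tolerance = 1e-6)
  expect_equal((n_of(al, th + h, p1) - n_of(al, th - h, p1)) / (2 * h),
               -(1 - p1) * al / th^2, tolerance = 1e-6)
  expect_equal((n_of(al, th, p1 + h) - n_of(al, th, p1 - h)) / (2 * h),
               -al / th, tolerance = 1e-6)
  # all-zero spreads give a zero RI spread
  a0 <- list(alpha = 0.197, theta = 0.734, dalpha = 0, dtheta = 0)
  pz <- inhomogeneity(0, 0, 0.9, 0, 1e14, "fixed")
  expect_equal(delta_n(pz, a0, a0)$d_n, 0, tolerance = 1e-7)
})

test_that("density spread vanishes at the decoupling composition", {
  a0 <- list(alpha = 0.197, theta = 1 / 0.997, dalpha = 0, dtheta = 0)
  p <- inhomogeneity(0, 0, 0.9, 0, 1e4, "binomial")
  expect_equal(delta_rho(p, a0, a0, water)$d_rho, 0, tolerance = 1e-12)
  # fixed Ns and identical spread-free components: no spread at all
  pz <- inhomogeneity(0, 0, 0.9, 0, 100, "fixed")
  az <- list(alpha = 0.2, theta = 0.7, dalpha = 0, dtheta = 0)
  expect_equal(delta_rho(pz, az, az, water)$d_rho, 0)
})

test_that("all propagated spreads scale as N0^(-1/2) without inhomogeneity", {
  a <- protein_comp(); b <- triolein_comp()
  get <- function(N0) {
    p <- inhomogeneity(0.5, 0, 0.9, 0, N0, "mass_fluctuation")
    u <- propagate_uncertainty(p, a, b, water)
    c(u$d_theta_eff, u$d_alpha_eff, u$d_phi1, u$d_n, u$d_rho)
  }
  for (N0 in c(1e3, 1e4, 1e5)) {
    ratio <- get(N0) / get(4 * N0)
    expect_true(all(abs(ratio - 2) < 0.02))
  }
})

test_that("RI and density spreads plateau when the solute mass fluctuates", {
  a <- protein_comp(); b <- triolein_comp()
  val <- function(N0) {
    p <- inhomogeneity(0.5, 0, 0.9, 0.05, N0, "mass_fluctuation")
    c(n = delta_n(p, a, b)$d_n, rho = delta_rho(p, a, b, water)$d_rho)
  }
  v <- vapply(c(1e5, 1e7, 1e9), val, numeric(2))
  expect_true(all(v > 0))
  # converged: the last doubling changes nothing appreciable
  expect_equal(v[, 2], v[, 3], tolerance = 1e-3)
  # strictly positive limits
  expect_gt(v["n", 3], 1e-4)
  expect_gt(v["rho", 3], 1e-4)
})

test_that("propagated totals equal the root-sum-square of their components", {
  a <- protein_comp(); b <- triolein_comp()
  p <- inhomogeneity(0.3, 0.05, 0.85, 0.02, 1e4, "mass_fluctuation")
  u <- propagate_uncertainty(p, a, b, water)
  expect_equal(u$d_n, sqrt(sum(u$components$n^2)), tolerance = 1e-12)
  expect_equal(u$d_rho, sqrt(sum(u$components$rho^2)), tolerance = 1e-12)
  expect_equal(u$d_phi1, sqrt(sum(u$components$phi1^2)), tolerance = 1e-12)
})
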