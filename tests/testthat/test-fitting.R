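test_that("pycnometry relations reproduce the calibration arithmetic", {
  # volume from a 4.9307 g water mass difference at 0.997 g/mL
  expect_equal(pycnometer_volume(104.9307, 100, 0.997), 4.9455, tolerance = 1e-4)
  expect_equal(pycnometer_volume(100.997, 100, 0.997), 1)
  # linear in the mass difference
  expect_equal(pycnometer_volume(108, 100, 0.997),
               2 * pycnometer_volume(104, 100, 0.997))
  expect_error(pycnometer_volume(99, 100, 0.997), "exceed")

  expect_equal(density_from_pycnometry(105.10, 100, 4.9455), 1.0312,
               tolerance = 1e-4)
  # water refill reproduces the calibration density
  v <- pycnometer_volume(104.9307, 100, 0.997)
  expect_equal(density_from_pycnometry(104.9307, 100, v), 0.997)
  # Gaussian propagation through the quotient matches finite differences
  m <- 105.1; mp <- 100; v <- 4.9455; dm <- 0.002; dv <- 0.0017
  h <- 1e-7
  gm <- (density_from_pycnometry(m + h, mp, v) - density_from_pycnometry(m - h, mp, v)) / (2 * h)
  gv <- (density_from_pycnometry(m, mp, v + h) - density_from_pycnometry(m, mp, v - h)) / (2 * h)
  analytic <- sqrt((dm / v)^2 + ((m - mp) / v^2 * dv)^2)
  expect_equal(sqrt((gm * dm)^2 + (gv * dv)^2), analytic, tolerance = 1e-6)
})

test_that("dilution bookkeeping yields the solute concentration", {
  # undiluted stock with 76% water: c_s = 0.24 rho
  expect_equal(dilution_concentration(10, 0, 0.76, 1.02), 0.24 * 1.02)
  expect_equal(dilution_concentration(5, 3, 1, 1.0), 0) # pure water stock
  # adding an equal water mass halves the solute mass fraction
  expect_equal(dilution_concentration(4, 4, 0.2, 1),
               dilution_concentration(4, 0, 0.2, 1) / 2)
})

test_that("noiseless synthetic series are recovered exactly", {
  s <- generate_synthetic_series(0.18, 0.734, c_grid = seq(0.02, 0.1, 0.02))
  fa <- fit_alpha(s)
  expect_equal(fa$alpha_hat, 0.18, tolerance = 1e-12)
  expect_equal(fa$residuals, rep(0, 5), tolerance = 1e-14)
  ft <- fit_theta(s)
  expect_equal(ft$theta_hat, 0.734, tolerance = 1e-12)
  # decoupled data: flat density, zero slope
  sd <- generate_synthetic_series(0.18, 1 / 0.997, c_grid = seq(0.02, 0.1, 0.02))
  ftd <- fit_theta(sd)
  expect_equal(ftd$slope, 0, tolerance = 1e-12)
  expect_equal(max(abs(ftd$residuals)), 0, tolerance = 1e-14)
  single <- concentration_series(0.05, dn = 0.01, solvent = water)
  expect_error(fit_alpha(single), "at least 2")
})

test_that("synthetic generation is seed-deterministic with correct noise model", {
  s1 <- generate_synthetic_series(0.197, 0.734, noise_dn = 5e-4,
                                  noise_rho = 1e-3, seed = 42)
  s2 <- generate_synthetic_series(0.197, 0.734, noise_dn = 5e-4,
                                  noise_rho = 1e-3, seed = 42)
  expect_identical(s1$dn, s2$dn)
  expect_identical(s1$rho, s2$rho)
  s3 <- generate_synthetic_series(0.197, 0.734, noise_dn = 5e-4, seed = 43)
  expect_false(identical(s1$dn, s3$dn))
  expect_equal(s1$dn_sd, rep(5e-4, 8))
})

test_that("milk-like and emulsion-like compositions give opposite density slopes", {
  # lactose + milk proteins: theta_eff < 1/rho1 -> density rises with RI
  mt <- material_table()
  sm <- solute_composition(list(mt$lactose, mt$casein, mt$whey_protein),
                           c(0.45, 0.35, 0.20), water)
  eff_sm <- composition_effective(sm)
  s_sm <- generate_synthetic_series(eff_sm$alpha_eff, eff_sm$theta_eff,
                                    c_grid = seq(0.02, 0.1, 0.02))
  expect_gt(fit_theta(s_sm)$slope, 0)
  # soybean-oil dominated emulsion: theta_eff > 1/rho1 -> falling density
  il <- solute_composition(list(mt$soybean_oil, mt$whey_protein),
                           c(0.9, 0.1), water)
  eff_il <- composition_effective(il)
  s_il <- generate_synthetic_series(eff_il$alpha_eff, eff_il$theta_eff,
                                    c_grid = seq(0.02, 0.1, 0.02))
  expect_lt(fit_theta(s_il)$slope, 0)
})

test_that("the md_fit model object exposes the standard methods", {
  s <- generate_synthetic_series(0.197, 0.734, noise_dn = 5e-4,
                                 noise_rho = 1e-3, seed = 17)
  fit <- fit_series(s)
  co <- coef(fit)
  expect_named(co, c("alpha", "theta"))
  expect_equal(unname(co["alpha"]), 0.197, tolerance = 0.05)
  expect_length(residuals(fit, "dn"), 8)
  expect_length(residuals(fit, "rho"), 8)
  # predict() evaluates the fitted density-RI line
  expect_equal(predict(fit, 0), 0.997)
  expect_equal(predict(fit, 0.02),
               unname(rho_from_contrast(0.02, co[["alpha"]], co[["theta"]], 0.997)))
  expect_output(print(fit), "alpha")
  # free-intercept variant recovers the solvent density on clean data
  s0 <- generate_synthetic_series(0.197, 0.734)
  # noiseless data: lm warns about a perfect fit, which is the point here
  ff <- suppressWarnings(fit_theta(s0, fix_intercept = FALSE))
  expect_equal(ff$intercept, 0.997, tolerance = 1e-10)
  expect_equal(ff$theta_hat, 0.734, tolerance = 1e-10)
})

test_that("interval coverage of the fitted parameters is nominal", {
  hits_a <- 0L; hits_t <- 0L
  n_rep <- 300L
  for (i in seq_len(n_rep)) {
    s <- generate_synthetic_series(0.197, 0.734, noise_dn = 5e-4,
                                   noise_rho = 1e-3, seed = 1000L + i)
    fa <- fit_alpha(s); ft <- fit_theta(s)
    hits_a <- hits_a + (abs(fa$alpha_hat - 0.197) <= fa$sd)
    hits_t <- hits_t + (abs(ft$theta_hat - 0.734) <= ft$sd)
  }
  expect_gt(hits_a / n_rep, 0.60)
  expect_lt(hits_a / n_rep, 0.76)
  expect_gt(hits_t / n_rep, 0.60)
  expect_lt(hits_t / n_rep, 0.76)
})

test_that("fit residuals on model-generated data are trendless", {
  n_sig <- 0L
  n_rep <- 200L
  for (i in seq_len(n_rep)) {
    s <- generate_synthetic_series(0.197, 0.734, noise_dn = 5e-4,
                                   c_grid = seq(0.01, 0.1, length.out = 10),
                                   seed = 5000L + i)
    r <- fit_alpha(s)$residuals
    p <- summary(stats::lm(r ~ s$c))$coefficients[2, 4]
    n_sig <- n_sig + (p < 0.05)
  }
  # about 5% false positives expected; flag a real trend well above that
  expect_lt(n_sig / n_rep, 0.12)
})

test_that("round-trip: fitted parameters reproduce the generating density line", {
  s <- generate_synthetic_series(0.197, 0.734, noise_dn = 3e-4,
                                 noise_rho = 5e-4, seed = 99)
  fit <- fit_series(s)
  dn_grid <- seq(0, 0.02, length.out = 5)
  truth <- rho_from_contrast(dn_grid, 0.197, 0.734, 0.997)
  est <- predict(fit, dn_grid)
  # combined parameter uncertainty bounds the deviation of the line
  tol <- 3 * (abs(dn_grid / coef(fit)["alpha"]) * fit$alpha$sd +
              0.997 * abs(dn_grid / coef(fit)["alpha"]) * fit$theta$sd + 1e-6)
  expect_true(all(abs(est - truth) <= tol))
})

test_that("mixing-rule comparison ranks the generating rule first", {
  # single material: the Biot-implied solute RI is exactly self-consistent
  m <- protein_comp(0, 0)
  comp <- solute_composition(list(m), 1, water)
  s <- generate_synthetic_series(m$alpha, m$theta, c_grid = seq(0.02, 0.1, 0.02))
  fit <- fit_series(s)
  cmp <- compare_mixing_rules(fit, comp)
  expect_equal(cmp$rule[1], "biot")
  expect_lt(cmp$discrepancy[1], 1e-10)
  expect_true(all(diff(cmp$discrepancy) >= 0))
  # noisy Biot-generated data still rank Biot first
  sn <- generate_synthetic_series(m$alpha, m$theta, noise_dn = 2e-4,
                                  noise_rho = 5e-4, seed = 12)
  cmpn <- compare_mixing_rules(fit_series(sn), comp)
  expect_equal(cmpn$rule[1], "biot")
  # zero-contrast series: all rules agree trivially at the solvent point
  expect_equal(predict(fit, 0), 0.997)
})

test_that("series CSV input round-trips", {
  s <- generate_synthetic_series(0.18, 0.7, noise_dn = 1e-4, noise_rho = 1e-3,
                                 seed = 3)
  csv <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(c = s$c, dn = s$dn, dn_sd = s$dn_sd,
                              rho = s$rho, rho_sd = s$rho_sd), csv,
                   row.names = FALSE)
  s2 <- read_concentration_series(csv)
  expect_equal(s2$c, s$c)
  expect_equal(fit_alpha(s2)$alpha_hat, fit_alpha(s)$alpha_hat)
})
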