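test_that("Lorentzian has the exact peak, half-maximum and unit area", {
  expect_equal(lorentzian(0, 1), 1 / pi)
  expect_equal(lorentzian(1, 1), 1 / (2 * pi))
  om <- seq(-4000, 4000, by = 0.05)
  expect_equal(trapz(om, lorentzian(om, 1)), 1, tolerance = 1e-3)
  expect_error(lorentzian(0, 0), class = "qens_invalid_parameter")
  expect_error(lorentzian(0, -1), class = "qens_invalid_parameter")
})

test_that("COM width follows gamma = hbar D q^2", {
  expect_equal(com_width(0, 1), 0)
  expect_equal(com_width(5, 1), 0.6582119 * 5)
  expect_equal(com_width(3, 2 * 0.7), 4 * com_width(3, 0.7))
  expect_error(com_width(-1, 1), class = "qens_invalid_parameter")
})

test_that("jump-diffusion width has Fickian, half-saturation and plateau limits", {
  hbar <- qens_constants()$hbar
  # Fickian limit at small q
  expect_equal(internal_width(2, 0.5, 1e-4), hbar * 2 * 1e-8,
               tolerance = 1e-6)
  # half saturation when D q^2 tau = 1
  D <- 4; tau <- 0.25; q <- 1  # D q^2 tau = 1
  expect_equal(internal_width(D, tau, q), hbar * D * q^2 / 2)
  # plateau hbar / tau at large q
  expect_equal(internal_width(2, 0.1, 1e3), hbar / 0.1, tolerance = 1e-4)
  expect_error(internal_width(-1, 0.1, 1), class = "qens_invalid_parameter")
})

test_that("internal mixture degenerates and peaks as expected", {
  om <- seq(-50, 50, by = 0.1)
  internal <- list(D1 = 10, tau1 = 0, D2 = 10, tau2 = 0, alpha = 0.3)
  # equal widths: a single Lorentzian regardless of alpha
  lam <- internal_width(10, 0, 1)
  expect_equal(internal_component(1, om, 2, internal),
               lorentzian(om, 2 + lam))
  # alpha = 1: pure first component
  internal2 <- list(D1 = 3, tau1 = 0.1, D2 = 40, tau2 = 0.01, alpha = 1)
  lam1 <- internal_width(3, 0.1, 1)
  expect_equal(internal_component(1, om, 0.5, internal2),
               lorentzian(om, 0.5 + lam1))
  # peak value with gamma = 0, alpha = 0.5, widths 2 and 10 ueV:
  # (0.5/pi) (1/2 + 1/10)
  hbar <- qens_constants()$hbar
  internal3 <- list(D1 = 2 / hbar, tau1 = 0, D2 = 10 / hbar, tau2 = 0,
                    alpha = 0.5)
  expect_equal(internal_component(1, 0, 0, internal3),
               (0.5 / pi) * (1 / 2 + 1 / 10))
  internal_bad <- list(D1 = 1, tau1 = 0, D2 = 1, tau2 = 0, alpha = 1.2)
  expect_error(internal_component(1, om, 1, internal_bad),
               class = "qens_invalid_parameter")
})

test_that("Voigt profile matches its limiting shapes and keeps unit area", {
  x <- seq(-600, 600, by = 0.05)
  # narrow Gaussian: Voigt -> Lorentzian
  expect_equal(voigt_profile(x, 1e-4, 2), lorentzian(x, 2), tolerance = 1e-6)
  # narrow Lorentzian: Voigt -> Gaussian
  expect_equal(voigt_profile(x, 1.5, 1e-8), dnorm(x, 0, 1.5),
               tolerance = 1e-6)
  xw <- seq(-4000, 4000, by = 0.1)
  expect_equal(trapz(xw, voigt_profile(xw, 1.5, 1)), 1, tolerance = 1e-3)
})

test_that("resolution model validates normalization and coverage", {
  cmp <- data.frame(amplitude = c(0.6, 0.4), center = c(-0.5, 0.8),
                    sigma = c(1.2, 1.8))
  res <- resolution_model(c(0.5, 1.0), list(cmp, cmp))
  expect_s3_class(res, "qens_resolution")
  expect_error(resolution_at(res, 0.7), class = "qens_config_error")
  bad <- data.frame(amplitude = c(0.6, 0.6), center = 0, sigma = 1)
  expect_error(resolution_model(0.5, list(bad)),
               class = "qens_invalid_parameter")
  # area of the resolution profile is 1
  om <- seq(-100, 100, by = 0.05)
  expect_equal(trapz(om, resolution_profile(res, 0.5, om)), 1,
               tolerance = 1e-9)
})

test_that("analytic resolution convolution has delta and sifting limits", {
  om <- seq(-80, 80, by = 0.2)
  # near-delta resolution: convolution returns the unconvolved Lorentzian
  res0 <- resolution_model(1, list(data.frame(amplitude = 1, center = 0,
                                              sigma = 1e-5)))
  mc <- list(list(kind = "lorentzian", weight = 1, gamma = 1.5))
  expect_equal(convolve_resolution(mc, res0, 1, om), lorentzian(om, 1.5),
               tolerance = 1e-8)
  # elastic delta against two off-center Gaussians: weighted Gaussian sum
  cmp <- data.frame(amplitude = c(0.7, 0.3), center = c(-2, 3),
                    sigma = c(1, 2))
  res2 <- resolution_model(1, list(cmp))
  got <- convolve_resolution(list(list(kind = "elastic", weight = 2)),
                             res2, 1, om)
  expect_equal(got, 2 * (0.7 * dnorm(om, -2, 1) + 0.3 * dnorm(om, 3, 2)))
})

test_that("analytic Voigt convolution agrees with the quadrature oracle", {
  om <- seq(-100, 100, by = 0.4)
  res <- make_resolution(0.55, fwhm = 3.5, n_components = 3, seed = 2)
  mc <- list(list(kind = "lorentzian", weight = 0.45, gamma = 1),
             list(kind = "lorentzian", weight = 0.3, gamma = 12),
             list(kind = "elastic", weight = 0.08))
  a <- convolve_resolution(mc, res, 0.55, om)
  n <- convolve_numeric(mc, res, 0.55, om)
  expect_lt(max(abs(a - n) / n), 1e-6)
  # single centered component, gamma = 1, sigma = 1 (the textbook Voigt)
  res1 <- resolution_model(1, list(data.frame(amplitude = 1, center = 0,
                                              sigma = 1)))
  mc1 <- list(list(kind = "lorentzian", weight = 1, gamma = 1))
  a1 <- convolve_resolution(mc1, res1, 1, om)
  n1 <- convolve_numeric(mc1, res1, 1, om)
  expect_lt(max(abs(a1 - n1) / n1), 1e-6)
})

test_that("convolution preserves area and linearity", {
  om <- seq(-4000, 4000, by = 0.25)
  res <- make_resolution(0.7, fwhm = 3.5, n_components = 3, seed = 5)
  mc_a <- list(list(kind = "lorentzian", weight = 0.6, gamma = 2))
  mc_b <- list(list(kind = "lorentzian", weight = 0.25, gamma = 9))
  ca <- convolve_resolution(mc_a, res, 0.7, om)
  cb <- convolve_resolution(mc_b, res, 0.7, om)
  cab <- convolve_resolution(c(mc_a, mc_b), res, 0.7, om)
  expect_equal(cab, ca + cb)                      # linearity
  expect_equal(trapz(om, ca), 0.6, tolerance = 1e-3)  # area conservation
})

test_that("full model evaluation reduces, scales and integrates correctly", {
  inst <- study_instrument()
  solv <- study_solvent(inst)
  om <- inst$omega_grid
  q <- inst$q_values[2]
  tr2 <- two_pop_truth(solv)
  # r = 1 reduces bit-identically to a single population at D_dil
  tr_r1 <- tr2; tr_r1$r <- 1
  tr_single <- single_truth(solv, D = 5)
  expect_identical(eval_model(q, om, tr_r1, inst$resolution, solv),
                   eval_model(q, om, tr_single, inst$resolution, solv))
  # protein-free limit: pure scaled solvent
  tr0 <- tr_single; tr0$beta <- 0; tr0$A0 <- 0; tr0$elastic_residual <- 0
  srow <- solv[abs(solv$q - q) < 1e-8, ]
  expect_equal(eval_model(q, om, tr0, inst$resolution, solv),
               convolve_resolution(list(list(kind = "lorentzian",
                                             weight = srow$beta,
                                             gamma = srow$gamma)),
                                   inst$resolution, q, om))
  # area: 2 beta + A0 + elastic_residual + beta_D2O (each line unit area;
  # COM and internal mixtures both carry amplitude beta)
  om_wide <- seq(-4000, 4000, by = 0.25)
  solv_narrow <- data.frame(q = q, beta = 0.15, gamma = 8)
  got <- trapz(om_wide, eval_model(q, om_wide, tr2, inst$resolution,
                                   solv_narrow))
  expect_equal(got, 2 * 0.8 + 0.05 + 0.01 + 0.15, tolerance = 2e-2)
  # symmetric in omega for centered resolution components
  sym <- eval_model(q, om, tr2, inst$resolution, solv)
  expect_equal(sym, rev(sym))
  # invalid ordering rejected
  tr_bad <- tr2; tr_bad$D_dense <- 7
  expect_error(eval_model(q, om, tr_bad, inst$resolution, solv),
               class = "qens_invalid_parameter")
})
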