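test_that("single-component resolution has the exact textbook sigma", {
  res <- make_resolution(c(0.4, 1.0), fwhm = 3.5, n_components = 1)
  cmp <- resolution_at(res, 0.4)
  expect_equal(cmp$sigma, 3.5 / (2 * sqrt(2 * log(2))), tolerance = 1e-12)
  expect_equal(cmp$sigma, 1.486, tolerance = 1e-3)
  expect_error(make_resolution(1, fwhm = -1), class = "qens_invalid_parameter")
})

test_that("multi-component resolutions are normalized with the requested fwhm", {
  res <- make_resolution(seq(0.4, 1.9, by = 0.15), fwhm = 3.5,
                         n_components = 3, seed = 1)
  for (q in res$q) {
    cmp <- resolution_at(res, q)
    expect_equal(sum(cmp$amplitude), 1, tolerance = 1e-12)
    # independent dense-scan fwhm measurement
    expect_equal(scan_fwhm(cmp), 3.5, tolerance = 0.02)
  }
})

test_that("infinite counts give the noiseless model and seeds are reproducible", {
  inst <- study_instrument()
  solv <- study_solvent(inst)
  tr <- single_truth(solv)
  sp_inf <- simulate_spectrum(inst, tr, counts_scale = Inf, seed = 3)
  direct <- eval_model(sp_inf[[2]]$q, inst$omega_grid, tr, inst$resolution,
                       solv)
  expect_identical(sp_inf[[2]]$intensity, direct)
  sp_a <- simulate_spectrum(inst, tr, counts_scale = 1e3, seed = 11)
  sp_b <- simulate_spectrum(inst, tr, counts_scale = 1e3, seed = 11)
  expect_identical(sp_a[[1]]$intensity, sp_b[[1]]$intensity)
  sp_c <- simulate_spectrum(inst, tr, counts_scale = 1e3, seed = 12)
  expect_false(identical(sp_c[[1]]$intensity, sp_a[[1]]$intensity))
})

test_that("counting noise averages out over replicates", {
  inst <- default_instrument(q_values = c(0.55, 1.0), omega_step = 2,
                             n_components = 1L)
  solv <- solvent_table(inst$q_values)
  tr <- single_truth(solv)
  noiseless <- eval_model(0.55, inst$omega_grid, tr, inst$resolution, solv)
  nrep <- 200
  acc <- matrix(0, nrep, length(inst$omega_grid))
  for (k in seq_len(nrep)) {
    acc[k, ] <- simulate_spectrum(inst, tr, counts_scale = 1e3,
                                  seed = k)[[1]]$intensity
  }
  m <- colMeans(acc)
  se <- apply(acc, 2, sd) / sqrt(nrep)
  expect_true(all(abs(m - noiseless) < 3.5 * se))
  # and the error column matches the empirical noise scale
  err <- simulate_spectrum(inst, tr, counts_scale = 1e3, seed = 1)[[1]]$error
  expect_equal(mean(apply(acc, 2, sd) / err), 1, tolerance = 0.05)
})

test_that("boundary intensity ratios reduce to single-population spectra", {
  inst <- study_instrument()
  solv <- study_solvent(inst)
  tr_r1 <- two_pop_truth(solv); tr_r1$r <- 1
  tr_r0 <- two_pop_truth(solv); tr_r0$r <- 0
  sp_r1 <- simulate_spectrum(inst, tr_r1, counts_scale = 1e3, seed = 7)
  sp_r0 <- simulate_spectrum(inst, tr_r0, counts_scale = 1e3, seed = 7)
  sp_dil <- simulate_spectrum(inst, single_truth(solv, D = 5),
                              counts_scale = 1e3, seed = 7)
  sp_den <- simulate_spectrum(inst, single_truth(solv, D = 1),
                              counts_scale = 1e3, seed = 7)
  for (i in seq_along(inst$q_values)) {
    expect_identical(sp_r1[[i]]$intensity, sp_dil[[i]]$intensity)
    expect_identical(sp_r0[[i]]$intensity, sp_den[[i]]$intensity)
  }
})

test_that("two-population quasi-elastic width lies between the two Fickian widths", {
  # COM-only spectrum: suppress internal broadening (lambda = 0), elastic
  # and solvent terms, with a near-delta resolution
  q <- 0.55
  res <- resolution_model(q, list(data.frame(amplitude = 1, center = 0,
                                             sigma = 1e-3)))
  inst <- instrument_config(seq(-100, 100, by = 0.002), q, res)
  tr <- ground_truth("two_population", D_dil = 5, D_dense = 1, r = 0.5,
                     internal = list(D1 = 0, tau1 = 0, D2 = 0, tau2 = 0,
                                     alpha = 0.5),
                     A0 = 0, beta = 0.5, elastic_residual = 0,
                     solvent = data.frame(q = q, beta = 0, gamma = 1))
  sp <- simulate_spectrum(inst, tr, counts_scale = Inf, seed = 1)[[1]]
  f <- sp$intensity
  half <- max(f) / 2
  hwhm <- max(abs(sp$omega[f >= half]))
  hbar <- qens_constants()$hbar
  expect_gt(hwhm, hbar * 1 * q^2)
  expect_lt(hwhm, hbar * 5 * q^2)
})

test_that("tie-line splitting obeys the lever rule exactly", {
  diagram <- phase_diagram_mock(center_cp = 240, width_cp = 160)
  # interior point at the salt midline: branches at 80 and 400 mg/mL
  total <- phase_composition(240, 27.5)
  sp <- split_composition(total, diagram)
  expect_true(sp$split)
  expect_equal(sp$dilute$c_p, 80)
  expect_equal(sp$dense$c_p, 400)
  expect_equal(sp$V_dense_star, 0.5)
  # boundary cases
  expect_equal(split_composition(phase_composition(80, 27.5),
                                 diagram)$V_dense_star, 0)
  expect_equal(split_composition(phase_composition(400, 27.5),
                                 diagram)$V_dense_star, 1)
  # outside the binodal: flagged, unchanged
  out <- split_composition(phase_composition(500, 27.5), diagram)
  expect_false(out$split)
  expect_equal(out$V_dense_star, 0)
  expect_identical(out$dense, phase_composition(500, 27.5))
})

test_that("lever-rule round trip is exact for random interior compositions", {
  diagram <- phase_diagram_mock()
  set.seed(99)
  n_ok <- 0
  for (k in 1:1000) {
    c_s <- runif(1, 20.5, 34.5)
    br <- qensllps:::binodal_branches(diagram, c_s)
    if (is.null(br)) next
    c_p <- runif(1, br["dilute"], br["dense"])
    sp <- split_composition(phase_composition(c_p, c_s), diagram)
    if (!sp$split) next
    rebuilt_p <- (sp$dense$c_p - sp$dilute$c_p) * sp$V_dense_star +
      sp$dilute$c_p
    rebuilt_s <- (sp$dense$c_s - sp$dilute$c_s) * sp$V_dense_star +
      sp$dilute$c_s
    expect_equal(rebuilt_p, c_p, tolerance = 1e-12)
    expect_equal(rebuilt_s, c_s, tolerance = 1e-12)
    # and lever_rule inverts split_composition exactly
    expect_equal(lever_rule(c_p, sp$dense$c_p, sp$dilute$c_p),
                 sp$V_dense_star, tolerance = 1e-12)
    n_ok <- n_ok + 1
  }
  expect_gt(n_ok, 900)
})
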