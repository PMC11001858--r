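test_that("zero-pressure BC is stationary", {
  spec <- bc_zp(87)
  expect_equal(bc_pressure(spec, "LACA", 0), 87)
  expect_equal(bc_pressure(spec, "LACA", 17.3), 87)
  expect_equal(bc_pressure(bc_zp(0), "RPCA", 5), 0)
  expect_error(bc_pressure(spec, "LICA", 0), "unknown outlet")
})

test_that("symmetrical-pressure BC adds the quadratic dynamic term", {
  areas <- setNames(rep(5e-6, 6), cow_vessels()$outlets)
  p_mean <- setNames(rep(87, 6), cow_vessels()$outlets)
  spec <- bc_sp(p_mean, c_n = c(ACA = 1, MCA = 1, PCA = 1), area = areas,
                rho = 1137)
  expect_equal(bc_pressure(spec, "LMCA", 0, Q = 0), 87)
  # hand-computed, unit by unit: 150 mL/min = 2.5e-6 m^3/s; v = Q/A = 0.5 m/s;
  # dynamic term = 0.5*1*1137*0.5^2 = 142.125 Pa = 1.06605 mmHg
  hand <- 87 + 0.5 * 1 * 1137 * (150 / 6e7 / 5e-6)^2 / 133.322
  expect_equal(bc_pressure(spec, "LMCA", 0, Q = 150), hand, tolerance = 1e-12)
  # doubling the flow quadruples the dynamic term
  d1 <- bc_pressure(spec, "LMCA", 0, Q = 150) - 87
  d2 <- bc_pressure(spec, "LMCA", 0, Q = 300) - 87
  expect_equal(d2, 4 * d1, tolerance = 1e-12)
})

test_that("DEP playback interpolates linearly with periodic extension", {
  p <- waveform(c(80, 90, 100, 90), 4, "LACA", "pressure")  # 1 s at 4 Hz
  spec <- bc_dep(list(LACA = p), f = 1)
  expect_equal(bc_pressure(spec, "LACA", 0.25), 90)
  expect_equal(bc_pressure(spec, "LACA", 0.125), 85)  # midpoint
  expect_equal(bc_pressure(spec, "LACA", 0.25 + 3), 90, tolerance = 1e-9)
  expect_error(bc_pressure(spec, "RPCA", 0), "unknown outlet")
  short <- waveform(c(80, 90), 4, "LACA", "pressure")
  expect_error(bc_dep(list(LACA = short), f = 1), "one period")
})

test_that("PM pressure evaluates the modulated-cosine form exactly", {
  spec <- bc_pm(c(LACA = 90), pi_p = 0.8, f = 1, phi = 0, beta = 0.5)
  expect_equal(bc_pressure(spec, "LACA", 0), 90 * (1 + 0.4 * cos(0.5)),
               tolerance = 1e-12)
  flat <- bc_pm(c(LACA = 90), pi_p = 0, f = 1, phi = 0.3, beta = 0)
  expect_equal(bc_pressure(flat, "LACA", c(0, 0.4, 2)), rep(90, 3))
  crest <- bc_pm(c(LACA = 90), pi_p = 0.8, f = 1, phi = 0, beta = 0)
  expect_equal(bc_pressure(crest, "LACA", 0), 90 * 1.4)
})

test_that("windkessel update has the RC fixed point and Euler step", {
  expect_equal(wm_update(1, 0, R = 1, C = 1, dt = 0.1), 0.9)
  # steady state p = R*Q is a fixed point
  expect_equal(wm_update(5, 2.5, R = 2, C = 1, dt = 0.3), 5)
  # trajectory tracks the closed-form relaxation within O(dt)
  p <- 0; R <- 2; C <- 0.5; Q <- 3; dt <- 0.01
  for (k in 1:200) p <- wm_update(p, Q, R, C, dt)
  exact <- R * Q * (1 - exp(-2 / (R * C)))
  expect_equal(p, exact, tolerance = 0.01)
  expect_error(wm_update(1, 0, R = 1, C = 1, dt = 2), "unstable")
  expect_warning(wm_update(1, 0, R = 1, C = 1, dt = 0.6), "poorly resolved")
})

test_that("resistance fitting recovers the generating law", {
  # exact linear data: p = R* Q
  Rstar <- 2e9
  Q <- make_sine(mean = 150, amp_frac = 0.4, vessel = "LMCA")
  p <- waveform(Pa_to_mmHg(Rstar * mlmin_to_m3s(Q$values)), 1000, "LMCA",
                "pressure")
  expect_equal(fit_resistance(p, Q), Rstar, tolerance = 1e-9 * Rstar)
  # steady single-point data
  Qc <- waveform(rep(150, 100), 100, "LMCA", "flow")
  pc <- waveform(rep(Pa_to_mmHg(Rstar * mlmin_to_m3s(150)), 100), 100,
                 "LMCA", "pressure")
  expect_equal(fit_resistance(pc, Qc, "mean"), Rstar, tolerance = 1e-9 * Rstar)
  expect_equal(fit_resistance(pc, Qc), Rstar, tolerance = 1e-9 * Rstar)
  # compliant ground truth biases the naive instantaneous fit only mildly
  C <- 8e-11
  pt <- generate_windkessel_truth(Rstar, C, Q,
                                  p0 = Pa_to_mmHg(Rstar * mlmin_to_m3s(150)))
  expect_equal(fit_resistance(pt, Q), Rstar, tolerance = 0.05 * Rstar)
  z <- waveform(rep(0, 100), 100, "LMCA", "flow")
  expect_error(fit_resistance(pc, z), "degenerate")
})

test_that("tau-uniform capacitance derivation", {
  caps <- derive_capacitances(c(ACA = 3, MCA = 2, PCA = 6), C_MCA = 3)
  expect_equal(caps$tau, 6)
  expect_equal(unname(caps$C["ACA"]), 2)
  expect_equal(unname(caps$C["PCA"]), 1)
  # all classes equal R -> all C equal C_MCA
  eq <- derive_capacitances(c(ACA = 2, MCA = 2, PCA = 2), C_MCA = 3)
  expect_equal(unname(eq$C), rep(3, 3))
  # the constraint R*C = tau holds per outlet
  expect_equal(unname(caps$R_outlet * caps$C_outlet), rep(6, 6),
               tolerance = 1e-12)
  expect_error(derive_capacitances(c(ACA = 3, PCA = 6), 3), "MCA")
})

test_that("PM fitting recovers generating parameters and their medians", {
  truth <- list(pi_p = 0.8, phi = -0.45, beta = 0.6)
  t <- (0:2999) / 1000
  outlets <- cow_vessels()$outlets
  p_means <- c(85, 86, 87, 86.5, 88.5, 89)
  pw <- setNames(lapply(seq_along(outlets), function(i) {
    waveform(p_means[i] * (1 + truth$pi_p / 2 *
                             pm_cosine(t, 1, truth$phi, truth$beta)),
             1000, outlets[i], "pressure")
  }), outlets)
  spec <- fit_pm_params(pw, f = 1)
  expect_equal(spec$pi_p, truth$pi_p, tolerance = 0.01 * truth$pi_p)
  expect_equal(spec$phi, truth$phi, tolerance = 0.01)
  expect_equal(spec$beta, truth$beta, tolerance = 0.01 * truth$beta)
  expect_equal(unname(spec$p_mean[outlets]), p_means, tolerance = 1e-3)
  # re-fitting a PM-generated waveform returns the same parameters
  regen <- setNames(lapply(outlets, function(o) {
    waveform(bc_pressure(spec, o, t), 1000, o, "pressure")
  }), outlets)
  spec2 <- fit_pm_params(regen, f = 1)
  expect_equal(spec2$pi_p, spec$pi_p, tolerance = 1e-6)
  expect_equal(spec2$phi, spec$phi, tolerance = 1e-6)
  expect_equal(spec2$beta, spec$beta, tolerance = 1e-6)
  # a pure cosine fits with essentially no modulation
  pure <- list(LACA = waveform(90 * (1 + 0.4 * cos(2 * pi * t)), 1000,
                               "LACA", "pressure"))
  expect_lt(abs(fit_pm_params(pure, f = 1)$beta), 0.01)
  # identical inputs give identical fits, and medians equal the common fit
  same <- setNames(lapply(outlets, function(o) {
    w <- pw$LACA; w$vessel <- o; w
  }), outlets)
  spec3 <- fit_pm_params(same, f = 1)
  fits <- attr(spec3, "fits")
  expect_lt(max(abs(fits$phi - fits$phi[1])), 1e-9)
  expect_equal(spec3$phi, fits$phi[1], tolerance = 1e-9)
  expect_equal(spec3$beta, fits$beta[1], tolerance = 1e-9)
})

test_that("side-averaged SP derivation and its consistency with ZP", {
  ws <- quiet_default_ws()
  ci <- segment_cycles(ws_get(ws, "LACA", "pressure"), 1)
  areas <- setNames(rep(5e-6, 6), cow_vessels()$outlets)
  spec <- suppressMessages(derive_sp_params(ws, areas = areas, ci = ci))
  # left/right members of each class share one side-averaged mean
  expect_equal(spec$p_mean[["LACA"]], spec$p_mean[["RACA"]])
  expect_equal(spec$p_mean[["LACA"]], (85 + 86) / 2, tolerance = 1e-3)
  expect_equal(spec$p_mean[["LPCA"]], (88.5 + 89) / 2, tolerance = 1e-3)
  # the mean over the six SP levels reproduces the ZP value: two averaging
  # routes over the same data agree
  zp <- derive_zp(ws, ci)
  expect_equal(mean(spec$p_mean), zp$p_zp, tolerance = 1e-9)
  # symmetric input: both sides equal the common cycle mean
  wsym <- ws
  for (cls in list(c("LACA", "RACA"), c("LMCA", "RMCA"), c("LPCA", "RPCA"))) {
    wsym$waveforms[[paste0(cls[2], "_p")]]$values <-
      wsym$waveforms[[paste0(cls[1], "_p")]]$values
  }
  ssym <- suppressMessages(derive_sp_params(wsym, areas = areas, ci = ci))
  expect_equal(ssym$p_mean[["LMCA"]],
               cycle_average(ws_get(wsym, "LMCA", "pressure"), ci),
               tolerance = 1e-12)
})
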