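test_that("segment lumping follows the Poiseuille and inertance laws", {
  geom <- data.frame(segment = "IN", node_a = "LICA", node_b = "LMCA",
                     length_mm = 100, diameter_mm = 3)
  net <- suppressWarnings(build_network(geom, fluid_props(mu = 4.01e-3)))
  # independent arithmetic: 128 * mu * l / (pi d^4)
  expect_equal(net$segments$R_seg,
               128 * 4.01e-3 * 0.1 / (pi * 0.003^4), tolerance = 1e-12)
  expect_equal(net$segments$L_seg,
               4 * 1137 * 0.1 / (pi * 0.003^2), tolerance = 1e-12)
  # doubling the diameter cuts the resistance 16-fold
  geom2 <- geom; geom2$diameter_mm <- 6
  net2 <- suppressWarnings(build_network(geom2))
  expect_equal(net$segments$R_seg / net2$segments$R_seg, 16,
               tolerance = 1e-12)
})

test_that("the complete Circle of Willis is cyclic and validated", {
  net <- build_network(cow_geometry())
  expect_gte(net$cycle_rank, 1)
  expect_setequal(net$inlets, cow_vessels()$inlets)
  expect_setequal(net$outlets, cow_vessels()$outlets)
  # without the ACoA the ring cannot close: acyclic, but only a warning
  g <- cow_geometry()
  expect_warning(build_network(g[g$segment != "ACoA", ]), "acyclic")
  # a disconnected graph is an error
  g2 <- cow_geometry()
  g2 <- g2[g2$segment != "BA", ]
  expect_error(build_network(g2), "disconnected")
  g3 <- cow_geometry(); g3$length_mm[1] <- -1
  expect_error(build_network(g3), "positive")
})

test_that("steady solve matches closed-form dividers and the dense oracle", {
  # identical branches split the inflow evenly
  sym <- build_network(y_geometry())
  st <- steady_solve(sym, c(LICA = 300),
                     c(LMCA = 87, RMCA = 87))
  expect_equal(unname(st$outlet_flows), c(150, 150), tolerance = 1e-9 * 150)
  # branch resistances R and 3R split 3:1 toward the easy branch
  asym <- build_network(y_geometry(len_b1 = 10, len_b2 = 30))
  st2 <- steady_solve(asym, c(LICA = 400), c(LMCA = 87, RMCA = 87))
  expect_equal(unname(st2$outlet_flows[["LMCA"]] / st2$outlet_flows[["RMCA"]]),
               3, tolerance = 1e-9)
  # zero inflow, unequal outlet pressures: pure recirculation dp / sum(R)
  st3 <- steady_solve(sym, c(LICA = 0), c(LMCA = 90, RMCA = 80))
  R_b <- poiseuille_R(y_geometry())[2:3]
  q_expect <- m3s_to_mlmin(mmHg_to_Pa(10) / sum(R_b))
  expect_equal(unname(st3$outlet_flows[["LMCA"]]), -q_expect,
               tolerance = 1e-9 * q_expect)
  expect_equal(unname(st3$outlet_flows[["RMCA"]]), q_expect,
               tolerance = 1e-9 * q_expect)
  # gauge invariance: shifting all outlet pressures leaves flows unchanged
  st4 <- steady_solve(sym, c(LICA = 300), c(LMCA = 40, RMCA = 40))
  expect_equal(st4$outlet_flows, st$outlet_flows, tolerance = 1e-12)
})

test_that("sparse solve equals an independent dense assembly on small networks", {
  # a 5-junction network with a loop, random-ish resistances via geometry
  geom <- data.frame(
    segment = c("s1", "s2", "s3", "s4", "s5", "s6", "s7"),
    node_a = c("LICA", "J1", "J1", "J2", "J3", "J2", "RVA"),
    node_b = c("J1", "J2", "J3", "J3", "LMCA", "RPCA", "J2"),
    length_mm = c(15, 22, 31, 9, 17, 26, 13),
    diameter_mm = c(4, 3.1, 2.4, 2.8, 2.6, 2.2, 3.4),
    stringsAsFactors = FALSE
  )
  net <- suppressWarnings(build_network(geom))
  inflow <- c(LICA = 250, RVA = 90)
  p_out <- c(LMCA = 88, RPCA = 86)
  st <- steady_solve(net, inflow, p_out)
  oracle <- dense_steady_oracle(geom, poiseuille_R(geom),
                                mlmin_to_m3s(inflow), mmHg_to_Pa(p_out))
  expect_equal(unname(st$segment_flows),
               unname(m3s_to_mlmin(oracle$q)), tolerance = 1e-9)
  expect_equal(unname(st$node_pressures[names(oracle$p)]),
               unname(Pa_to_mmHg(oracle$p)), tolerance = 1e-9)
  expect_lt(st$residual, 1e-9)
  # and on the full Circle of Willis
  cow <- build_network(cow_geometry())
  infl <- c(LICA = 249.5, RICA = 241, LVA = 87.8, RVA = 80.9)
  pout <- setNames(c(85, 86, 87, 86.5, 88.5, 89), cow_vessels()$outlets)
  stc <- steady_solve(cow, infl, pout)
  oc <- dense_steady_oracle(cow_geometry(), poiseuille_R(cow_geometry()),
                            mlmin_to_m3s(infl), mmHg_to_Pa(pout))
  expect_equal(unname(stc$segment_flows), unname(m3s_to_mlmin(oc$q)),
               tolerance = 1e-9)
})

test_that("transient solver conserves mass and honours imposed BCs", {
  ws <- quiet_default_ws()
  net <- build_network(cow_geometry())
  sim <- run_bc_set(net, ws, "dep", n_cycles = 2)
  expect_lt(max(sim$residual), 1e-9)
  # DEP playback is sample-exact: the imposed outlet pressure trace equals
  # the recorded pressure at every step
  for (v in c("LACA", "RPCA")) {
    expect_lt(max(abs(sim$outlet_pressure[[v]]$values -
                        ws_get(ws, v, "pressure")$values[1:2000])), 1e-9)
  }
})

test_that("symmetric network with a symmetric BC gives symmetric flows", {
  sym <- build_network(y_geometry())
  inflow <- list(LICA = make_sine(mean = 300, amp_frac = 0.5, n_cycles = 1))
  sim <- simulate_network(sym, inflow, bc_zp(87, c("LMCA", "RMCA")),
                          n_cycles = 2)
  expect_lt(max(abs(sim$outlet_flow$LMCA$values - sim$outlet_flow$RMCA$values)),
            1e-9 * 150)
})

test_that("inertial transient relaxes to the steady resistive solution", {
  net <- build_network(y_geometry(len_b1 = 10, len_b2 = 30))
  inflow <- list(LICA = waveform(rep(400, 1000), 1000, "LICA", "flow"))
  pout <- c(LMCA = 87, RMCA = 87)
  st <- steady_solve(net, c(LICA = 400), pout)
  # resistive mode reproduces it exactly from the first step
  sim_r <- simulate_network(net, inflow, bc_zp(87, names(pout)),
                            n_cycles = 1, inertance = FALSE)
  expect_equal(unname(vapply(sim_r$outlet_flow, function(w) tail(w$values, 1),
                             numeric(1))),
               unname(st$outlet_flows), tolerance = 1e-9)
  # with inertance, starting from rest, it converges after the transient
  sim_i <- simulate_network(net, inflow, bc_zp(87, names(pout)),
                            n_cycles = 1, init = "zero")
  expect_equal(unname(vapply(sim_i$outlet_flow, function(w) tail(w$values, 1),
                             numeric(1))),
               unname(st$outlet_flows), tolerance = 1e-6)
})

test_that("windkessel outlets relax to p = R*Q under constant inflow", {
  net <- build_network(pipe_geometry())
  Rw <- c(LMCA = 4e9); Cw <- c(LMCA = 5e-11)  # tau = 0.2 s
  spec <- bc_wm(Rw, Cw, p0 = c(LMCA = 0))
  inflow <- list(LICA = waveform(rep(150, 1000), 1000, "LICA", "flow"))
  sim <- simulate_network(net, inflow, spec, n_cycles = 2, f = 1)
  p_final <- tail(sim$outlet_pressure$LMCA$values, 1)
  p_expect <- Pa_to_mmHg(4e9 * mlmin_to_m3s(150))
  expect_equal(p_final, p_expect, tolerance = 0.005 * p_expect)
})

test_that("removing outlet-pressure differences shifts flow toward the posterior", {
  # the reference outlet means place posterior pressures above anterior ones;
  # a uniform (ZP) pressure therefore under-pressurises the posterior outlets
  # and pulls flow from the anterior to the posterior circulation
  net <- build_network(cow_geometry())
  infl <- c(LICA = 249.5, RICA = 241, LVA = 87.8, RVA = 80.9)
  sp_means <- setNames(c(85.5, 85.5, 86.75, 86.75, 88.75, 88.75),
                       cow_vessels()$outlets)
  st_sp <- steady_solve(net, infl, sp_means)
  st_zp <- steady_solve(net, infl, setNames(rep(mean(sp_means), 6),
                                            names(sp_means)))
  posterior <- c("LPCA", "RPCA")
  anterior <- c("LACA", "RACA")
  post_share <- function(st) sum(st$outlet_flows[posterior]) /
    sum(st$outlet_flows)
  ant_share <- function(st) sum(st$outlet_flows[anterior]) /
    sum(st$outlet_flows)
  expect_gt(post_share(st_zp), post_share(st_sp))
  expect_lt(ant_share(st_zp), ant_share(st_sp))
})

test_that("missing BC coverage and unstable settings are rejected", {
  net <- build_network(pipe_geometry())
  inflow <- list(LICA = waveform(rep(150, 1000), 1000, "LICA", "flow"))
  expect_error(simulate_network(net, inflow, bc_zp(87, "RMCA")), "LMCA")
  unstable <- bc_wm(c(LMCA = 1e6), c(LMCA = 1e-10), p0 = c(LMCA = 0))
  expect_error(simulate_network(net, inflow, unstable, dt = 0.001),
               "unstable")
})
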