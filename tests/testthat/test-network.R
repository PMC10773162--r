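# Lumped-parameter dissection network: elements, solver, occlusion

test_that("segment resistance follows the Poiseuille closed form", {
  newt <- power_law_params(consistency_index_K = 0.004, exponent_n = 1)
  R <- segment_resistance(100, 5, newt)
  expect_equal(R, 8 * 0.004 * 0.1 / (pi * 0.005^4), tolerance = 1e-12)
  # doubling the radius divides resistance by 16
  expect_equal(segment_resistance(100, 10, newt), R / 16, tolerance = 1e-12)
  # power-law lumping at the reference shear rate: independent log-space
  # viscosity oracle
  pl <- power_law_params(0.08, 0.55)
  eta100 <- 0.08 * exp(-0.45 * log(100))
  expect_equal(segment_resistance(100, 5, pl, reference_shear_rate = 100),
               8 * eta100 * 0.1 / (pi * 0.005^4), tolerance = 1e-12)
})

test_that("tear orifice law is odd, anchored at zero, and has the derived quadratic loss", {
  te <- tear_element(5, discharge_coefficient = 0.6, density = 1022)
  expect_equal(tear_dp(te, 0), 0)
  q <- c(1e-6, 5e-6, 2e-5, 1e-4)
  expect_equal(tear_dp(te, -q), -tear_dp(te, q))
  expect_true(all(diff(tear_dp(te, q)) > 0))
  # quadratic coefficient by independent hand evaluation:
  # rho Q^2 / (2 Cd^2 (pi d^2 / 4)^2), Q = 1 L/min, d = 5 mm
  Q <- 1 / 60000
  A <- pi * 0.005^2 / 4
  dp_quad_hand <- 1022 * Q^2 / (2 * 0.6^2 * A^2)
  expect_equal(tear_dp(te, Q) - te$R_lin * Q, dp_quad_hand, tolerance = 1e-12)
  # inverse law consistency
  expect_equal(lumenflow:::tear_q(te, tear_dp(te, 3e-5)), 3e-5,
               tolerance = 1e-12)
})

test_that("steady single tube + RCR recovers series resistances", {
  R_seg <- 5e6
  net <- single_tube_network(R_seg = R_seg, Rp = 2, C = 1e-3, Rd = 20,
                             Pout = 5)
  sim <- solve_network(net, dt = 1e-3)
  Q <- 2                                           # L/min steady
  p_out_exact <- 5 + Q * (2 + 20)                  # mmHg
  p_in_exact <- p_out_exact +
    R_seg * (Q / 60000) / lumenflow:::MMHG_PA
  expect_rel(mean(sim$node_pressure_mmHg["n_out", ]), p_out_exact, 0.002)
  expect_rel(mean(sim$node_pressure_mmHg["n_in", ]), p_in_exact, 0.002)
  expect_rel(mean(sim$element_flow_L_min["s1", ]), Q, 1e-6)
})

test_that("parallel resistive branches split flow as a current divider", {
  R1 <- 2e6; R2 <- 6e6
  segs <- data.frame(id = c("b1", "b2", "s3"),
                     from = c("n0", "n0", "n1"), to = c("n1", "n1", "n2"),
                     R = c(R1, R2, 1e6), L = 0)
  net <- dissection_network(
    segs, NULL,
    outlets = list(list(node = "n2", params = windkessel_params(2, 1e-3, 20))),
    inlet = list(node = "n0",
                 waveform = flow_waveform(seq(0, 0.9, 0.1), rep(3, 10),
                                          period_s = 1)))
  sim <- solve_network(net, dt = 1e-3)
  q1 <- mean(sim$element_flow_L_min["b1", ])
  q2 <- mean(sim$element_flow_L_min["b2", ])
  expect_rel(q1 / q2, R2 / R1, 1e-9)
  expect_rel(q1 + q2, 3, 1e-9)
})

test_that("mass is conserved at every node and step to 1e-9 of peak inflow", {
  w <- make_inlet_waveform(0.78, 10, 0.35, 40)
  net <- build_network(make_case("S1-like"), w)
  sim <- solve_network(net, dt = 1e-3)
  expect_lte(sim$convergence$max_residual_rel, 1e-9)
  expect_true(sim$convergence$periodic)
})

test_that("solver solution agrees with an independent dense nonlinear solve", {
  w <- make_inlet_waveform(0.78, 10, 0.35, 40)
  net <- build_network(make_case("S1-like"), w)
  dt <- 1e-3
  sim <- solve_network(net, dt = dt)
  expect_dense_equivalence(net, sim, dt, nsteps = 5, tol = 1e-8)
})

test_that("halving the time step changes cycle-mean pressures by < 0.5%", {
  w <- make_inlet_waveform(0.8, 8, 0.4, 40)
  net <- single_tube_network(R_seg = 2e6, L_seg = 5e5, Rp = 3, C = 2e-3,
                             Rd = 30, Pout = 0, inflow = w)
  m1 <- rowMeans(solve_network(net, dt = 2e-3,
                               periodicity_tol = 1e-5)$node_pressure_mmHg)
  m2 <- rowMeans(solve_network(net, dt = 1e-3,
                               periodicity_tol = 1e-5)$node_pressure_mmHg)
  expect_lt(max(abs(m1 - m2) / abs(m2)), 0.005)
})

test_that("occluding a tear reproduces the reduced-communication case", {
  w <- make_inlet_waveform(0.78, 10, 0.35, 20)
  n2 <- build_network(make_case("S2-like"), w)
  n2m <- occlude_tear(n2, "reentry21")
  ref <- build_network(make_case("S2mod-like"), w)
  expect_equal(n2m$tears$open, ref$tears$open)
  expect_equal(n2m$tears$id, ref$tears$id)
  expect_error(occlude_tear(n2, "nosuch"), "unknown")
  expect_error(occlude_tear(n2m, "reentry21"), "already closed")
})

test_that("occluding one mid tear shifts the distal TL flow fraction", {
  w <- make_inlet_waveform(0.78, 10, 0.35, 40)
  net <- build_network(make_case("S2-like"), w)
  m_full <- report_metrics(solve_network(net, dt = 1e-3))
  m_occl <- report_metrics(solve_network(occlude_tear(net, "reentry21"),
                                         dt = 1e-3))
  d <- m_full$tl_pct[m_full$station == "P6"] -
    m_occl$tl_pct[m_occl$station == "P6"]
  expect_gt(abs(d), 1e-3)
})

test_that("false lumen behind a single open tear is a sealed pouch with no net flow", {
  w <- make_inlet_waveform(0.78, 10, 0.35, 20)
  net <- occlude_tear(build_network(make_case("S1-like"), w), "distal")
  expect_true(net$fl_sealed)
  expect_output(print(net), "sealed pouch")
  sim <- solve_network(net, dt = 1e-3)
  fl_ids <- net$segments$id[grepl("^FL", net$segments$id)]
  expect_lt(max(abs(sim$element_flow_L_min[fl_ids, ])), 1e-9)
  expect_lt(abs(mean(sim$element_flow_L_min["entry", ])), 1e-9)
})

test_that("symmetric TL/FL twin network has identically zero CLPD", {
  # two identical lumens between the same proximal and distal nodes: the
  # cross-lumen pressure difference at the twin mid-nodes vanishes by
  # symmetry up to solver precision
  segs <- data.frame(id = c("TL_a", "TL_b", "FL_a", "FL_b"),
                     from = c("join0", "tlm", "join0", "flm"),
                     to = c("tlm", "join1", "flm", "join1"),
                     R = 2e6, L = 1e5)
  net <- dissection_network(
    segs, NULL,
    outlets = list(list(node = "join1", params = windkessel_params(3, 2e-3, 30))),
    inlet = list(node = "join0",
                 waveform = make_inlet_waveform(0.8, 6, 0.4, 20)),
    stations = list(mid = list(tl_node = "tlm", fl_node = "flm",
                               tl_seg = "TL_a", fl_seg = "FL_a")))
  sim <- solve_network(net, dt = 1e-3)
  clpd <- sim$node_pressure_mmHg["flm", ] - sim$node_pressure_mmHg["tlm", ]
  expect_lt(max(abs(clpd)), 1e-8)
  m <- report_metrics(sim)
  expect_equal(m$tl_pct, 50, tolerance = 1e-8)
})
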