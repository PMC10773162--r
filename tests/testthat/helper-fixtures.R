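# Shared fixtures, built in code at test time.

# noise-free straight-tube acquisition, moderately fine grid
tube_field <- function(radius_mm = 12, length_mm = 40, voxel_mm = 2,
                       peak = 10, frames = 12, period = 0.8, seed = 7) {
  make_phantom_field(
    phantom_spec(kind = "straight_tube", radius_mm = radius_mm,
                 length_mm = length_mm, cycle_period_s = period,
                 peak_inlet_flow_L_min = peak, rng_seed = seed),
    acquisition_params(frames_per_cycle = frames, voxel_mm = voxel_mm,
                       noise_sd_fraction_of_venc = 0))
}

two_lumen_field <- function(tl_fraction = 0.56, voxel_mm = 1.5, frames = 12,
                            noise = 0, seed = 11) {
  make_phantom_field(
    phantom_spec(kind = "two_lumen_dissection", radius_mm = 12,
                 length_mm = 30, tl_flow_fraction = tl_fraction,
                 peak_inlet_flow_L_min = 8, rng_seed = seed),
    acquisition_params(frames_per_cycle = frames, voxel_mm = voxel_mm,
                       noise_sd_fraction_of_venc = noise))
}

# uniform axial velocity field inside a circular tube (for exact checks)
uniform_tube_field <- function(v_cm_s = 30, radius_mm = 10, voxel_mm = 1,
                               frames = 4, period = 1) {
  n <- ceiling(2 * (radius_mm + voxel_mm) / voxel_mm)
  nz <- 10
  cc <- (seq_len(n) - (n + 1) / 2) * voxel_mm
  inside <- outer(cc^2, cc^2, "+") < radius_mm^2
  mask2d <- matrix(0L, n, n); mask2d[inside] <- 1L
  mask <- array(rep(mask2d, nz), dim = c(n, n, nz))
  v <- array(0, dim = c(n, n, nz, frames, 3))
  for (k in seq_len(frames))
    v[, , , k, 3] <- array(rep(ifelse(inside, v_cm_s, 0), nz),
                           dim = c(n, n, nz))
  velocity_field(v, mask, rep(voxel_mm, 3),
                 (seq_len(frames) - 1) * period / frames, period,
                 origin_mm = c(cc[1], cc[1], voxel_mm / 2))
}

# small resistive test network: inlet -> segment -> node -> RCR outlet
single_tube_network <- function(R_seg = 1e6, L_seg = 0,
                                Rp = 2, C = 1e-3, Rd = 20, Pout = 5,
                                inflow = flow_waveform(seq(0, 0.9, 0.1),
                                                       rep(2, 10),
                                                       period_s = 1)) {
  dissection_network(
    segments = data.frame(id = "s1", from = "n_in", to = "n_out",
                          R = R_seg, L = L_seg),
    tears = NULL,
    outlets = list(list(node = "n_out",
                        params = windkessel_params(Rp, C, Rd, Pout))),
    inlet = list(node = "n_in", waveform = inflow))
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / max(abs(expected), .Machine$double.eps),
            tol)
}

# independent dense nonlinear re-solve of the nodal system at sampled steps:
# reconstructs the implicit-Euler states entering each step from the stored
# solution, inverts the orifice law by root bracketing (uniroot), and solves
# the full system with pracma::fsolve from a perturbed start
expect_dense_equivalence <- function(net, sim, dt, nsteps = 5, tol = 1e-8,
                                     seed = 99) {
  nodes <- intersect(net$nodes, net$solvable_nodes)
  seg <- net$segments
  sact <- which(seg$from %in% nodes & seg$to %in% nodes)
  topen <- which(net$tears$open)
  MMHG <- lumenflow:::MMHG_PA; LM <- lumenflow:::LMIN_M3S
  RP <- MMHG / LM; CP <- 1e-3 / MMHG
  t_grid <- sim$time_s
  Qin_all <- lumenflow:::wave_interp(net$inlet$waveform, t_grid) * LM
  set.seed(seed)
  steps <- sample(3:length(t_grid), nsteps)
  for (k in steps) {
    P_ref <- sim$node_pressure_mmHg[nodes, k] * MMHG
    Q_prev <- sim$element_flow_L_min[seg$id[sact], k - 1] * LM
    resid <- function(P) {
      names(P) <- nodes
      r <- stats::setNames(numeric(length(nodes)), nodes)
      for (e in seq_along(sact)) {
        i <- sact[e]
        q <- ((P[seg$from[i]] - P[seg$to[i]]) + (seg$L[i] / dt) * Q_prev[e]) /
          (seg$R[i] + seg$L[i] / dt)
        r[seg$from[i]] <- r[seg$from[i]] + q
        r[seg$to[i]] <- r[seg$to[i]] - q
      }
      for (j in topen) {
        te <- net$tear_elems[[j]]
        dp <- P[net$tears$from[j]] - P[net$tears$to[j]]
        q <- if (abs(dp) < 1e-14) 0 else
          stats::uniroot(function(x) te$R_lin * x + te$b * x * abs(x) - dp,
                         interval = c(-1, 1), tol = 1e-18)$root
        r[net$tears$from[j]] <- r[net$tears$from[j]] + q
        r[net$tears$to[j]] <- r[net$tears$to[j]] - q
      }
      for (jj in seq_along(net$outlets)) {
        o <- net$outlets[[jj]]
        Rp <- o$params$Rp * RP; Rd <- o$params$Rd * RP
        C <- o$params$C * CP; Pout <- o$params$Pout * MMHG
        alpha <- 1 / (1 + dt / (Rd * C)); beta <- alpha * dt / C
        g <- 1 / (Rp + beta)
        q_ref <- sim$outlet_flow_L_min[jj, k] * LM
        s_out <- sim$node_pressure_mmHg[o$node, k] * MMHG - q_ref / g
        r[o$node] <- r[o$node] + g * (P[o$node] - s_out)
      }
      r[net$inlet$node] <- r[net$inlet$node] - Qin_all[k]
      unname(r)
    }
    sol <- pracma::fsolve(resid, x0 = P_ref * (1 + 1e-4), tol = 1e-14)
    expect_lt(max(abs(sol$x - P_ref)) / max(abs(P_ref)), tol)
  }
}

# steady power-law Poiseuille: u(r) = u_max (1 - (r/R)^((n+1)/n)),
# wall shear rate (3n+1)/n * Q / (pi R^3)  (Rabinowitsch-Mooney)
powerlaw_poiseuille_field <- function(Q_m3s, R_mm = 8, voxel = 1, n_pl = 0.55,
                                      frames = 3) {
  m <- (n_pl + 1) / n_pl
  R_m <- R_mm / 1000
  u_max <- (3 * n_pl + 1) / (n_pl + 1) * Q_m3s / (pi * R_m^2)   # m/s
  # grid aligned so that a voxel centre sits exactly at the probe point
  # x = R - 0.25 voxel on the +x axis
  nside <- ceiling(2 * R_mm / voxel) + 4
  off <- (R_mm - 0.25 * voxel) %% voxel
  cc <- (seq_len(nside) - ceiling(nside / 2)) * voxel + off
  r2 <- outer(cc^2, cc^2, "+")
  inside <- r2 < R_mm^2
  prof <- ifelse(inside, u_max * (1 - (sqrt(r2) / R_mm)^m), 0) * 100  # cm/s
  nz <- 6
  v <- array(0, dim = c(nside, nside, nz, frames, 3))
  for (k in seq_len(frames))
    v[, , , k, 3] <- array(rep(prof, nz), dim = c(nside, nside, nz))
  mask2d <- matrix(0L, nside, nside); mask2d[inside] <- 1L
  velocity_field(v, array(rep(mask2d, nz), dim = c(nside, nside, nz)),
                 rep(voxel, 3), (seq_len(frames) - 1) / frames, 1,
                 origin_mm = c(cc[1], cc[1], voxel / 2))
}

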