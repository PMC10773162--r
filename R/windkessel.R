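#' Three-element Windkessel (RCR) parameters
#'
#' Lumped outlet boundary condition: a proximal (characteristic) resistance
#' `Rp` in series with a parallel compliance `C` / distal resistance `Rd`
#' combination discharging to a reference distal pressure `Pout`.
#'
#' @param Rp Proximal resistance, mmHg min/L; `Rp < Rd` (arterial convention).
#' @param C Compliance, L/mmHg.
#' @param Rd Distal resistance, mmHg min/L.
#' @param Pout Reference distal pressure, mmHg. Default 0.
#' @return An object of class `windkessel_params`.
#' @export
windkessel_params <- function(Rp, C, Rd, Pout = 0) {
  stopifnot(Rp > 0, Rd > 0, C > 0)
  if (Rp >= Rd)
    stop("Rp must be smaller than Rd (arterial convention)")
  structure(list(Rp = Rp, C = C, Rd = Rd, Pout = Pout),
            class = "windkessel_params")
}

#' @export
print.windkessel_params <- function(x, ...) {
  cat(sprintf("RCR Windkessel: Rp = %.4g, Rd = %.4g mmHg.min/L, C = %.4g L/mmHg, Pout = %.4g mmHg\n",
              x$Rp, x$Rd, x$C, x$Pout))
  invisible(x)
}

#' Pressure calibration targets
#'
#' @param mean_pressure Target cycle-mean outlet pressure, mmHg.
#' @param pulse_pressure Target pulse pressure (systolic minus diastolic),
#'   mmHg, non-negative.
#' @return An object of class `pressure_targets`.
#' @export
pressure_targets <- function(mean_pressure, pulse_pressure) {
  stopifnot(pulse_pressure >= 0, mean_pressure > pulse_pressure / 2)
  structure(list(mean_pressure = mean_pressure,
                 pulse_pressure = pulse_pressure),
            class = "pressure_targets")
}

# periodic linear interpolation of a waveform at arbitrary times within [0, T)
wave_interp <- function(w, t) {
  tt <- c(w$time_s, w$period_s)
  vv <- c(w$flow, w$flow[1])
  stats::approx(tt, vv, xout = t %% w$period_s, rule = 2)$y
}

#' Simulate an RCR Windkessel outlet
#'
#' Integrates the compliance state `C dPc/dt = Q - (Pc - Pout)/Rd` with
#' implicit (backward) Euler and reports the outlet face pressure
#' `P = Pc + Q Rp` over the final cycle, run cycle-by-cycle until the
#' cycle-mean pressure changes by less than `periodicity_tol` (relative)
#' between consecutive cycles.
#'
#' @param params A [windkessel_params()].
#' @param inflow A [flow_waveform()] prescribing the outlet inflow, L/min.
#' @param dt Time step in seconds; must not exceed the inflow sampling
#'   interval.
#' @param max_cycles Maximum number of cycles before giving up (default 100).
#' @param periodicity_tol Relative change in cycle-mean pressure accepted as
#'   periodic (default 1e-3, i.e. 0.1 percent).
#' @param Pc0 Initial compliance pressure; defaults to the DC solution
#'   `Pout + mean(Q) Rd`.
#' @return A list of class `rcr_pressure`: `time_s`, `pressure_mmHg` (final
#'   cycle), `period_s`, `cycles`, `converged`, `mean_mmHg`, `pulse_mmHg`.
#' @export
simulate_rcr <- function(params, inflow, dt = 1e-3, max_cycles = 100,
                         periodicity_tol = 1e-3, Pc0 = NULL) {
  stopifnot(inherits(params, "windkessel_params"),
            inherits(inflow, "flow_waveform"), dt > 0, max_cycles >= 1)
  if (dt > min(diff(c(inflow$time_s, inflow$period_s))) + 1e-12)
    stop("dt must not exceed the inflow sampling interval")
  T <- inflow$period_s
  n <- max(4L, round(T / dt))
  dt <- T / n
  t <- (seq_len(n) - 1) * dt
  Q <- wave_interp(inflow, t)
  qbar <- mean(Q)
  a <- dt / (60 * params$C)                 # dt in s, C in L/mmHg, Q in L/min
  denom <- 1 + a / params$Rd
  if (is.null(Pc0)) {
    # the compliance recurrence is linear with constant coefficients, so the
    # exactly periodic initial state follows from one pass and the cyclic
    # closure Pc0 = B / (1 - A), A = denom^-n
    pc <- 0
    for (k in seq_len(n)) pc <- (pc + a * (Q[k] + params$Pout / params$Rd)) / denom
    Pc0 <- pc / (1 - denom^(-n))
  }
  Pc <- Pc0
  prev_mean <- Inf
  converged <- FALSE
  P <- numeric(n)
  cyc <- 0L
  while (cyc < max_cycles) {
    cyc <- cyc + 1L
    for (k in seq_len(n)) {
      Pc <- (Pc + a * (Q[k] + params$Pout / params$Rd)) / denom
      P[k] <- Pc + Q[k] * params$Rp
    }
    m <- mean(P)
    if (is.finite(prev_mean) &&
        abs(m - prev_mean) <= periodicity_tol * max(abs(m), 1e-12)) {
      converged <- TRUE
      break
    }
    prev_mean <- m
  }
  if (!converged)
    stop(sprintf(paste0("RCR simulation did not reach periodicity in %d cycles",
                        " (last cycle-mean change %.3g mmHg)"),
                 max_cycles, abs(mean(P) - prev_mean)))
  structure(list(time_s = t, pressure_mmHg = P, period_s = T, cycles = cyc,
                 converged = converged, mean_mmHg = mean(P),
                 pulse_mmHg = max(P) - min(P)),
            class = "rcr_pressure")
}

#' @export
print.rcr_pressure <- function(x, ...) {
  cat(sprintf("RCR outlet pressure: mean %.2f mmHg, pulse %.2f mmHg (%d cycles to periodicity)\n",
              x$mean_mmHg, x$pulse_mmHg, x$cycles))
  invisible(x)
}

#' Calibrate an RCR Windkessel from flow and pressure targets
#'
#' Replicates the usual boundary-condition tuning step: the total resistance
#' is fixed by the mean pressure, `R_total = (mean_pressure - Pout) / mean(Q)`,
#' split as `Rp = rp_fraction * R_total` and `Rd = (1 - rp_fraction) *
#' R_total`; the compliance is then found by bisection on the simulated pulse
#' pressure (which decreases strictly with `C`) until it matches the target
#' within `tol_mmHg` and the `C` bracket is tight.
#'
#' @param inflow A [flow_waveform()] with positive cycle-mean flow.
#' @param targets A [pressure_targets()].
#' @param rp_fraction Fraction of the total resistance assigned to the
#'   proximal element, in (0, 0.5). Default 0.1.
#' @param Pout Reference distal pressure, mmHg.
#' @param dt,tol_mmHg Simulation step and pulse-pressure tolerance.
#' @return An object of class `rcr_fit` with components `params`
#'   ([windkessel_params()]), `targets`, `achieved` (mean/pulse from the
#'   final simulation), `inflow`, `iterations`. Methods: `coef`, `print`,
#'   `summary`, `predict` (pressure waveform for new inflow), `residuals`.
#' @examples
#' w <- make_inlet_waveform(0.8, 6, 0.4, 40)
#' fit <- calibrate_rcr(w, pressure_targets(60, 25))
#' coef(fit)
#' @export
calibrate_rcr <- function(inflow, targets, rp_fraction = 0.1, Pout = 0,
                          dt = 1e-3, tol_mmHg = 0.5) {
  stopifnot(inherits(inflow, "flow_waveform"),
            inherits(targets, "pressure_targets"),
            rp_fraction > 0, rp_fraction < 0.5)
  qbar <- cycle_mean(inflow)
  if (qbar <= 0) stop("cycle-mean inflow must be positive")
  r_total <- (targets$mean_pressure - Pout) / qbar
  if (r_total <= 0) stop("mean pressure target must exceed Pout")
  Rp <- rp_fraction * r_total
  Rd <- (1 - rp_fraction) * r_total

  pulse_of <- function(C)
    simulate_rcr(windkessel_params(Rp, C, Rd, Pout), inflow, dt = dt,
                 periodicity_tol = 1e-6)$pulse_mmHg
  c_lo <- 1e-6; c_hi <- 10
  p_lo <- pulse_of(c_lo)   # small C -> large pulse
  p_hi <- pulse_of(c_hi)
  tp <- targets$pulse_pressure
  if (tp > p_lo || tp < p_hi)
    stop(sprintf(paste0("pulse-pressure target %.3g mmHg is outside the",
                        " achievable range [%.3g, %.3g] mmHg for this R split"),
                 tp, p_hi, p_lo))
  it <- 0L
  repeat {
    it <- it + 1L
    cm <- sqrt(c_lo * c_hi)
    pm <- pulse_of(cm)
    if (pm > tp) c_lo <- cm else c_hi <- cm
    if ((abs(pm - tp) < tol_mmHg && (c_hi / c_lo - 1) < 5e-3) || it >= 80)
      break
  }
  C <- sqrt(c_lo * c_hi)
  params <- windkessel_params(Rp, C, Rd, Pout)
  sim <- simulate_rcr(params, inflow, dt = dt, periodicity_tol = 1e-6)
  structure(list(params = params, targets = targets,
                 achieved = list(mean_pressure = sim$mean_mmHg,
                                 pulse_pressure = sim$pulse_mmHg),
                 inflow = inflow, iterations = it, dt = dt),
            class = "rcr_fit")
}

#' @export
print.rcr_fit <- function(x, ...) {
  cat("Calibrated 3-element Windkessel\n")
  print(x$params)
  cat(sprintf("  targets: mean %.4g / pulse %.4g mmHg; achieved: %.4g / %.4g mmHg (%d bisection steps)\n",
              x$targets$mean_pressure, x$targets$pulse_pressure,
              x$achieved$mean_pressure, x$achieved$pulse_pressure,
              x$iterations))
  invisible(x)
}

#' @export
coef.rcr_fit <- function(object, ...) {
  with(object$params, c(Rp = Rp, C = C, Rd = Rd, Pout = Pout))
}

#' @export
summary.rcr_fit <- function(object, ...) {
  out <- list(coef = coef(object), targets = object$targets,
              achieved = object$achieved,
              residuals = residuals(object))
  class(out) <- "summary.rcr_fit"
  out
}

#' @export
print.summary.rcr_fit <- function(x, ...) {
  cat("Windkessel calibration summary\n  parameters:\n")
  print(x$coef)
  cat(sprintf("  pressure residuals (achieved - target): mean %+.3g, pulse %+.3g mmHg\n",
              x$residuals["mean"], x$residuals["pulse"]))
  invisible(x)
}

#' @export
residuals.rcr_fit <- function(object, ...) {
  c(mean = object$achieved$mean_pressure - object$targets$mean_pressure,
    pulse = object$achieved$pulse_pressure - object$targets$pulse_pressure)
}

#' @export
predict.rcr_fit <- function(object, inflow = object$inflow, ...) {
  simulate_rcr(object$params, inflow, dt = object$dt, periodicity_tol = 1e-6)
}
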