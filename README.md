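# lumenflow

Quantitative hemodynamics of type B aortic dissection (TBAD) in R.

In TBAD a tear in the inner aortic wall creates a second flow channel — the
false lumen (FL) — alongside the original true lumen (TL), separated by the
dissection flap. Whether the FL keeps expanding depends on how blood is
exchanged between the lumina through the entry tear and any re-entry tears.
`lumenflow` packages the analysis chain used to study this question from
time-resolved (4D-flow MRI style) velocity data and lumped-parameter
modelling:

- **Rheology** — shear-thinning power-law blood viscosity
  η(γ̇) = K γ̇ⁿ⁻¹ (defaults K = 0.08 Pa·sⁿ, n = 0.55, ρ = 1022 kg/m³) with a
  low-shear floor, and the wall stress law τ = K γ̇ⁿ.
- **Flow metrics** — through-plane flow waveforms from voxel velocity
  fields with TL/FL masks, TL/FL flow distribution, peak velocities,
  area-weighted arch-branch flow splitting, flux-conservative inlet-profile
  extraction, and the reverse flow index
  RFI = 100·|∫Q₋dt| / (|∫Q₋dt| + |∫Q₊dt|),
  including the tear-direction conventions (forward = TL→FL at the entry
  tear, FL→TL at re-entry tears).
- **Wall shear stress** — near-wall one-sided shear-rate estimation and
  time-averaged wall shear stress, TAWSS = (1/T)∫|τ|dt.
- **Windkessel** — three-element (RCR) outlet simulation and calibration
  from a measured flow waveform and mean/pulse pressure targets, returned as
  a classed model object with `coef`, `summary`, `predict`, `residuals`.
- **0D dissection network** — a lumped-parameter surrogate of the dissected
  aorta: TL/FL segment chains (resistance + inertance), tear orifice
  elements ΔP = R·Q + ρ/(2·Cd²·A²)·Q|Q|, RCR outlets, implicit-Euler time
  stepping with a per-step Newton solve, run to a periodic state. Used for
  tear-configuration experiments: a two-tear baseline ("S1-like"), a
  four-tear state ("S2-like"), and the counterfactual with one mid tear
  occluded ("S2mod-like").
- **Morphometry** — lumen volumes from segmentation stacks (slice area ×
  thickness), maximum axial Feret diameters, and multiplicative composition
  of percent volume changes across follow-up intervals.
- **Synthetic data** — a pulsatile two-lumen phantom emulating a 4D-flow
  acquisition (39.2 ms temporal resolution, 2 mm voxels, VENC 150 cm/s,
  Gaussian velocity noise), so the entire pipeline runs and is tested
  without any scanner data.

The exact pressures and flow splits of a subject-specific 3D CFD study are
not reproducible by a 0D surrogate; the network is built to reproduce the
*mechanism* — opening re-entry tears redistributes flow from FL to TL and
lowers FL pressure and the cross-lumen pressure difference (CLPD) — and its
directional ordering is what `validate_trends()` asserts.

## Worked example

```r
library(lumenflow)

## blood rheology
pl <- power_law_params()
apparent_viscosity(pl, c(1, 100))
#> [1] 0.08000000 0.01007140        # Pa.s at 1 and 100 1/s

## calibrate an RCR outlet from an inlet waveform and pressure targets
w   <- make_inlet_waveform(period_s = 0.78, peak_flow_L_min = 10,
                           systolic_fraction = 0.35, frames = 40)
fit <- calibrate_rcr(w, pressure_targets(60, 30))
fit
#> Calibrated 3-element Windkessel
#> RCR Windkessel: Rp = 2.704, Rd = 24.34 mmHg.min/L, C = 0.003335 L/mmHg, Pout = 0 mmHg
#>   targets: mean 60 / pulse 30 mmHg; achieved: 60 / 30 mmHg (12 bisection steps)

## solve the four-tear dissection network and report station metrics
net <- build_network(make_case("S2-like"), w)
sim <- solve_network(net, dt = 1e-3)
sim
#> Dissection network solution: 10 nodes, 780 steps/cycle, periodic after 14 cycles
#>   max Kirchhoff residual: 9.88e-13 (relative to peak inlet flow)
report_metrics(sim)
#>   station tl_pct fl_pct rfi_tl rfi_fl mean_fl_pressure_mmHg peak_clpd_mmHg
#> 1      P2   60.5   39.5 0.0000   21.5                  60.4        0.00158
#> 2      P3   60.5   39.5 0.0000   21.5                  60.4        0.33068
#> 3      P4   66.2   33.8 0.0000   24.9                  60.4        0.52855
#> 4      P5   72.7   27.3 0.0000   28.2                  60.3        0.90405
#> 5      P6   78.5   21.5 0.0103   28.2                  60.3        0.90405
```

Reading the table: near the entry tear (P2) the FL carries ~40% of the
descending-aorta flow; moving distally the re-entry tears return flow to
the TL, whose share rises to ~79% at P6. The FL reverse flow index grows
distally, FL pressure sits slightly above TL pressure (positive CLPD,
< 1 mmHg here), and mass balance holds to 10⁻¹² of the peak inlet flow.

The full comparative study — generate phantom data, verify the flow
metrics on it, calibrate outlets, solve all three scenarios and check the
directional trends — is one call:

```r
report <- run_pipeline(default_run_config(seed = 1), outdir = "out")
validate_trends(report)
```

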