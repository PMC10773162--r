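---
title: "Models and methods behind lumenflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lumenflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lumenflow)
```

`lumenflow` analyses the hemodynamics of type B aortic dissection: how blood
distributes between the true lumen (TL) and false lumen (FL), how much of it
flows backwards, what shear it exerts on the wall, and how the pressures in
the two lumina compare — and how all of these respond to the number and size
of the tears connecting the lumina. This vignette explains the models, the
parameters that matter, the numerical choices, and what the synthetic data
do and do not establish.

## Blood rheology

Blood is treated as an incompressible shear-thinning power-law fluid,

$$\eta(\dot\gamma) = K\,\dot\gamma^{\,n-1}, \qquad
  \tau_w = \eta(\dot\gamma_w)\,\dot\gamma_w = K\,\dot\gamma_w^{\,n},$$

with defaults $K = 0.08$ Pa·sⁿ, $n = 0.55$ and density
$\rho = 1022$ kg·m⁻³. For $n<1$ the apparent viscosity diverges as
$\dot\gamma \to 0$, and no low-shear cutoff is standard; we clamp the
viscosity below a shear-rate floor of 0.01 s⁻¹ (configurable). The floor
applies to the viscosity only, so the wall stress still satisfies
$\tau(0)=0$ exactly and remains monotone in $\dot\gamma$. At $n=1$ the
model reduces identically to a Newtonian fluid of viscosity $K$ — a useful
closed-form limit that the tests exploit.

## Velocity-field metrics

A `velocity_field` holds the three velocity components (cm/s) on a regular
voxel grid over cardiac phases, plus an integer mask (0 background, 1 TL,
2 FL). Metrics are evaluated on analysis planes whose unit normal points
distally and defines positive flow.

*Integration rule.* Midpoint rule in space (a regular in-plane point grid
at a configurable pitch, each point weighted by pitch²), trapezoid rule in
time with periodic closure (the sample at $t=T$ equals the first sample and
is never stored). The midpoint rule is exact for uniform fields, and the
trapezoid rule is the natural quadrature for periodic sampled waveforms.

*Masked interpolation.* Velocities are interpolated trilinearly, but a
plain trilinear stencil near the wall blends in zero-velocity background
voxels and biases flow low by several percent at clinical resolutions. We
therefore interpolate $v\cdot\mathbf{1}_{lumen}$ and divide by the
interpolated indicator (a normalized, Shepard-style correction), and gate
sample points by the nearest-voxel mask label. With this correction a
uniform field integrates to $vA$ within rasterization error (<1% at
0.4 mm pitch), and the phantom's prescribed waveform is recovered within 2%
with 8 voxels across the diameter and 0.5% with 16.

*Reverse flow index.* For a signed net waveform $Q(t)$ over one period,

$$\mathrm{RFI} = 100\,
  \frac{\left|\int_0^T Q_-\,dt\right|}
       {\left|\int_0^T Q_-\,dt\right| + \left|\int_0^T Q_+\,dt\right|},$$

with $Q_+=\max(Q,0)$, $Q_-=\min(Q,0)$. An all-zero waveform returns 0 (the
0/0 convention, documented and tested). The index could alternatively be
accumulated voxel-wise before forming the ratio; we compute it from the net
lumen waveform, which matches its usual definition for plane measurements
and makes RFI$(-Q) = 100 -$ RFI$(Q)$ an exact identity. Through tears the
forward direction is TL→FL at the entry tear and FL→TL at re-entry tears;
`tear_rfi()` encodes this by negating re-entry waveforms, so a single
signed convention (positive = TL→FL) runs through the code and sign errors
cannot hide.

*Flow distribution.* TL/FL percentages are formed from cycle-mean net
flows, one number per plane (per-frame distributions are noisy and not what
a single-number-per-plane comparison needs). When a lumen's net flow is
non-positive the percentages leave $[0,100]$; the result is flagged rather
than suppressed.

## Wall shear stress

The wall shear rate is estimated by a first-order one-sided difference: the
tangential velocity magnitude at a probe depth $d$ inside the lumen divided
by $d$, with the wall velocity zero by no-slip. The default
$d = 0.25$ voxel keeps the probe in the first near-wall cell, which is as
deep as a first-order estimate stays informative at 2 mm voxels;
higher-order stencils are deliberately out of scope. The viscosity entering
$\tau = \eta(\dot\gamma_w)\dot\gamma_w$ is evaluated at the *estimated*
wall shear rate (a consistent nonlinear closure), not at a fixed reference
shear. TAWSS is the cycle average of $|\tau|$ by the same periodic
trapezoid rule. On a steady power-law pipe flow the estimate reproduces the
Rabinowitsch–Mooney wall stress
$\tau_w = K\,[(3n{+}1)/n \cdot Q/(\pi R^3)]^{\,n}$ within 5% at 16 voxels
across the diameter.

## Three-element Windkessel outlets

Each outlet is an RCR element: proximal resistance $R_p$, compliance $C$
discharging through distal resistance $R_d$ to a reference pressure
$P_{out}$, with

$$C\,\frac{dP_c}{dt} = Q - \frac{P_c - P_{out}}{R_d}, \qquad
  P = P_c + Q R_p.$$

Integration is implicit Euler. Because the recurrence is linear with
constant coefficients, the exactly periodic initial state follows from one
pass over the cycle and the cyclic closure $P_c(0) = B/(1-A)$ with
$A = \prod \text{(decay factors)}$; the periodicity loop (cycle-mean change
below 0.1% by default) then terminates almost immediately for any
parameter values — important because the calibration bisection visits
compliances spanning many decades, where naive transient integration can
need thousands of cycles.

Calibration follows the usual boundary-condition tuning logic: the mean
pressure fixes $R_{total} = (\bar P - P_{out})/\bar Q$; a fraction
`rp_fraction` (default 0.1, the conventional characteristic-impedance
share) goes to $R_p$; and $C$ is found by bisection on the simulated pulse
pressure, which is strictly decreasing in $C$ (verified over two decades).
The achievable pulse range is bounded below by $R_p\,(Q_{max}-Q_{min})$ —
the large-$C$ limit — and targets outside the range produce an error naming
the bound. Units are clinical outside (mmHg, L/min), SI inside, with
1 mmHg = 133.322 Pa fixed.

Defaults for the bundled scenario family: mean 60 mmHg, pulse 30 mmHg,
$P_{out}=0$. With the half-sine inlet used here (peak-to-mean ratio ≈ 4.5)
the large-$C$ pulse floor at `rp_fraction = 0.1` is ≈ 27 mmHg, so a pulse
target of 30 mmHg is comfortably attainable while remaining physiological
for a juvenile swine; lower targets would require a smaller proximal
fraction.

## The 0D dissection network

The 3D dissected aorta is lumped into a node/element graph:

- **Segments** (one per inter-tear region per lumen: 5 TL, 3 FL):
  Poiseuille resistance $8\eta(\dot\gamma_{ref})L/(\pi r^4)$ with the
  power-law viscosity at a reference shear rate (default 100 s⁻¹, a typical
  aortic wall shear scale), plus inertance $\rho L/A$. The wall is rigid —
  all compliance lives in the outlets.
- **Tears**: orifice elements
  $\Delta P = R_{lin} Q + \dfrac{\rho}{2 C_d^2 A^2}\,Q|Q|$, with
  $C_d = 0.6$ (sharp-edged orifice convention) and a linear term from
  Poiseuille flow through the 2 mm flap thickness. The law is odd and
  strictly increasing; its inverse is evaluated in the rationalized form
  $Q = 2\Delta P/(R_{lin} + \sqrt{R_{lin}^2 + 4b|\Delta P|})$, which avoids
  catastrophic cancellation when $R_{lin}^2 \gg 4b|\Delta P|$.
- **Outlets**: three lumped arch-branch RCRs at the arch node (splitting
  $1-f_{desc}$ of the mean flow by branch area) and one distal RCR
  ($f_{desc}$, default 0.42, between the two measured descending-aorta
  flow shares measured at the two emulated cardiac states), each calibrated by
  `calibrate_rcr()`.
- **Inlet**: a prescribed flow waveform at the arch node.

Time stepping is implicit Euler (default $dt = 1$ ms) with a damped Newton
solve of the nodal Kirchhoff system at every step — the orifice laws are
the only nonlinearity, so the Jacobian is the constant linear conductance
matrix plus rank-limited tear contributions. Newton iterates to $10^{-12}$
of the peak inlet flow, with a stall exit accepted only below $10^{-10}$
relative (round-off for flows of order $10^{-4}$ m³/s sits near
$10^{-16}$ absolute). Cycles repeat until cycle-mean node pressures change
by less than 0.1%. Mass balance at every node and step is part of the
solution report and is asserted at $10^{-9}$ relative in the tests,
alongside an independent cross-check: the nodal system is re-solved at
random time steps by `pracma::fsolve` with the orifice law inverted by root
bracketing, agreeing with the Newton path to $10^{-8}$.

### Geometry of the default case family

Tear stations sit 70/210/260/320 mm from the arch. The created mid
re-entry tears are 5 mm in diameter; the entry and distal tears default to
22 and 12 mm, their measured maximum axial extents. This matters: with all
four tears at 5 mm the distal orifice throttles the FL so strongly in the
two-tear baseline that the distal TL-fraction ordering across scenarios
inverts. With the measured entry/distal sizes the surrogate reproduces the
in vivo pattern: FL flow slightly exceeding TL flow near the entry tear in
the four-tear state, TL share rising distally, and all three directional
trends below. Lumen radii default to 7 mm (TL) and 9 mm (FL), consistent
with the measured maximum diameters; they are fixtures of the surrogate,
not subject measurements. Stations P2–P6 map schematically onto the
inter-tear regions (P2/P3 proximal/distal in the entry-to-first-mid-tear
region, P4 and P5 in the two following regions, P6 just proximal of the
distal tear with TL flow taken distal of the last station).

### Tear-configuration experiments and trends

`make_case()` builds the two-tear baseline ("S1-like"), the four-tear state
("S2-like") and the counterfactual with the first mid tear occluded
("S2mod-like"); `occlude_tear()` converts one into another and is verified
to reproduce `make_case()` structurally. `validate_trends()` asserts
directions only:

1. distal TL flow fraction: S2 ≥ S2mod ≥ S1;
2. mean FL pressure: S2 ≤ S2mod ≤ S1;
3. peak cross-lumen pressure difference: S2 ≤ S1.

`sweep_mid_tear()` interpolates continuously between S2mod-like and
S2-like by sweeping the first mid tear from closed to 5 mm with the second
mid tear open; on the default family all three metrics are monotone along
this sweep. A noteworthy feature of the surrogate: sweeping the *other* mid
tear alone (the S1→S2mod leg) leaves FL pressure and CLPD monotone but
produces a shallow (~0.1 percentage point) dip in distal TL fraction,
because a small mid tear initially increases proximal FL inflow before the
added return path dominates. The scenario-level ordering is unaffected;
the dip is a genuine property of orifice-coupled lumina, not numerical
noise.

A FL connected to fewer than two open tears is a dead-end pouch in a rigid
network: the solver flags it, and its element flows vanish identically.

## Synthetic acquisitions

The phantom emulates a clinical 4D-flow protocol: 39.2 ms temporal
resolution, 20 frames/cycle, 2 mm isotropic voxels, VENC 150 cm/s, additive
Gaussian velocity noise with SD a fraction of VENC (default 0.05), and two
cardiac states (0.78 s and 1.08 s cycles). The inlet waveform is a
half-sine systolic pulse (systolic fraction 0.35) with zero diastolic flow;
its cycle mean, $2 f_{sys} Q_{peak}/\pi$, is a closed-form oracle. The
axial profile is quasi-parabolic, rescaled each frame so the discrete plane
flow equals the prescribed waveform exactly — chosen over Womersley
profiles precisely because it admits exact oracles; pulsatile profile
shapes, k-space effects, phase wrap and eddy-current offsets are out of
scope. Consequently, passing tests establish the correctness of the
*metrics* (integration, masking, interpolation, unit handling, noise
robustness at the imposed SNR), not the physiological realism of the
velocity fields. The two-lumen phantom's imposed TL share (default 0.56)
is a free parameter of the generator, not a claim about any subject.

All generators are deterministic given `rng_seed`; the pipeline embeds the
seed and a configuration hash in every artifact, and repeated runs are
byte-identical.

## Morphometry

Lumen volume is slice area × thickness with centre-sampling pixel
membership, converging at first order to $\pi r^2 L$ on cylinder phantoms
(within 1% at 0.5 mm pixels). The maximum axial diameter is the per-slice
Feret (caliper) maximum over the convex hull of the labelled pixel
*squares* — each pixel contributes its corners, so a single-pixel region
measures the pixel diagonal and rasterized circles and ellipses are
recovered within one pixel diagonal. Diameters are in-plane only; oblique
reslicing and registration between scans are out of scope.

Percent changes between follow-ups compose multiplicatively,
$100\,(\prod_i (1 + c_i/100) - 1)$ — exact, associative and
order-independent. Note that published interval tables are not always
mutually consistent under this composition (rounding and re-segmentation
between scans); only compositions that close on a printed whole-interval
row are meaningful checks, and that is what the acceptance suite uses.

## Problem sizes and runtimes

The test suite runs phantoms of 14–33 voxels per side with 4–12 frames,
networks of ≤ 12 nodes at $dt = 1$–2 ms over 8–15 cycles, a 20-point tear
sweep, and two full pipeline runs — sizes chosen so every oracle is exact
or analytic and the whole suite completes in a few minutes on one core
while still exercising each code path at realistic resolution ratios
(voxels per diameter, frames per cycle, steps per cycle) of the emulated
protocol.

## Known limitations

- The 0D network reproduces mechanisms and orderings, not the absolute
  pressures or flow splits of a subject-specific 3D simulation; absolute
  CLPD magnitudes in particular are below 3D values.
- Rigid wall and rigid flap: no fluid–structure interaction, no flap
  motion; outlet compliance is the only capacitance.
- No FL thrombosis, tear growth, or oscillatory shear index.
- The phantom's quasi-parabolic profile underestimates near-wall velocity
  gradients of real pulsatile flow; TAWSS values on phantom data are
  validated against closed forms, not against scanner data.
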