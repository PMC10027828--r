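---
title: "Methods: pulsatile Casson flow in an idealized coiled aneurysm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pulsatile Casson flow in an idealized coiled aneurysm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## What the package models

`aneuflow` simulates blood flow through a parent vessel carrying a
side-wall saccular aneurysm, before and after endovascular coiling, and
computes the wall quantities that hemodynamic studies of rupture risk
revolve around: wall shear stress (WSS), its magnitude averaged over a
cardiac cycle (TAWSS), the oscillatory shear index (OSI), and wall
pressure at the peak-systolic and early-diastolic phases of the cycle.

Three modelling ingredients interact:

1. **Non-Newtonian rheology.** Blood is shear-thinning with a small
   yield stress. We use the Casson law
   \[
   \mu(\dot\gamma) \;=\; \Bigl(\sqrt{\tau_y/\dot\gamma} +
   \sqrt{\mu_\infty}\Bigr)^2,
   \qquad \dot\gamma = \sqrt{2\,D\!:\!D},
   \]
   with \(D\) the rate-of-strain tensor. Hematocrit \(H\) (red-cell
   volume fraction) sets the coefficients through a
   Merrill/Einstein-type parameterization,
   \(\tau_y(H) = 0.1\,(0.625H)^3\) Pa and
   \(\mu_\infty(H) = \eta_p (1-H)^{-5/2}\) with plasma viscosity
   \(\eta_p = 1.45\) mPa s. At the reference \(H = 0.40\) this gives
   \(\tau_y \approx 1.6\) mPa and \(\mu_\infty \approx 5.3\) mPa s.
   Both formulas are overridable (`casson_params()`), since published
   Casson fits for blood vary considerably; what matters for the
   porosity/hematocrit experiments is that both coefficients rise
   monotonically with \(H\).

2. **The coil as a porous medium.** A deployed coil of wire diameter
   \(d_w\) and length \(L_c\) occupies volume \(\pi d_w^2 L_c/4\) of
   the sac volume \(V_{sac}\); the porosity is the remaining fluid
   fraction. The reference coil (0.254 mm wire, 30 cm, 103.87 mm³ sac)
   gives \(\varepsilon = 0.854\). Flow through the pack feels a Darcy
   sink \(-(\mu_{app}/k)\,u\) applied over sac cells only. Permeability
   anchors \(k(0.75) = 3.7\times10^{-8}\) and
   \(k(0.85) = 5.4\times10^{-8}\) m² are interpolated linearly in
   porosity; the two anchor rows are not consistent with a single
   Carman–Kozeny constant, so no analytic porosity–permeability law is
   fitted — the anchors are taken as ground truth. \(\varepsilon = 1\)
   disables the sink *identically* (the permeability sentinel is
   `Inf`, so \(\mu/k\) is exactly zero and an uncoiled run is bitwise
   identical to a run without the coil model).
   No Forchheimer (inertial) term is included: only permeability is
   available to parameterize it, and sac velocities under coiling are
   small; the Darcy term is the minimal faithful model.

3. **Pulsatile driving.** The inlet section-mean velocity is a mean
   plus two cosine harmonics phased so the unique maximum falls at peak
   systole, \(t_{sys} = 0.24\) s of a \(T = 0.8\) s cycle, with the
   early-diastole sampling phase at 0.54 s:
   \(v(t) = \bar v\,(1 + 0.8\cos\theta + 0.2\cos 2\theta)\),
   \(\theta = 2\pi (t-t_{sys})/T\). Defaults \(\bar v = 0.25\) m/s,
   peak 0.5 m/s, minimum 0.1 m/s (strictly positive: no inflow
   reversal; the period mean is exactly \(\bar v\)). The spatial inlet
   profile is parabolic (centerline \(1.5\bar v\)). The cardiac period
   is configurable; the phase times scale with it.

## Geometry and meshing

The 3D patient geometry that motivates this pipeline is deliberately
idealized to a 2D plane: a straight channel of height \(D\) (vessel
diameter, default 3 mm) with a circular-bulge sac — the major segment
of a circle of diameter 5 mm cut by a 2.5 mm neck chord lying on the
upper wall. The solver physics (Casson rheology, Darcy sink, index
definitions) are dimension-agnostic; 2D keeps every experiment
desk-scale and fully reproducible from code. The cost is that absolute
index magnitudes and 3D secondary-flow features (swirl through the
ostium, dome impingement angle) are not comparable to patient cases;
only directional comparisons across rheologies and porosities are
meaningful here, and the test suite treats them exactly that way
(soft pass/warn trends, hard checks only for invariants and closed
forms).

Meshing is structured: a graded channel grid with geometric
boundary-layer rows at both walls (default 3 rows, ratio 1.3), and the
sac filled by scaling its boundary loop toward the circle center in
graded rings, conforming with the channel nodes along the neck chord.
All triangles are positively oriented; boundary edges carry
`INLET` / `OUTLET` / `WALL_VESSEL` / `WALL_SAC` tags and cells carry
`LUMEN` / `SAC` regions, preserved through Gmsh MSH 4.1 round trips.
Halving the target element size roughly quadruples the element count,
and the meshed sac area converges to the analytic circular-segment
area (both are tested).

## Discretization and solver

Equal-order linear (P1–P1) triangular finite elements with SUPG/PSPG
stabilization; the viscous term is kept in stress-divergence form
\(\nabla\!\cdot\!\bigl(\mu_{app}(\nabla u + \nabla u^T)\bigr)\) so that
the natural outlet condition is zero traction and wall traction is the
physically meaningful stress vector. The stabilization parameter is
the standard inverse-quadrature-sum form
\(\tau = \rho\,\bigl[(2\rho/\Delta t)^2 + (2\rho|u|/h)^2 +
(4\mu/h^2)^2 + \sigma^2\bigr]^{-1/2}\) with \(\sigma = \mu/k\) the
Darcy coefficient.

Each time step (implicit Euler by default, BDF2 optional) is solved by
Picard outer iterations: convection and the apparent viscosity are
evaluated at the previous iterate, the Darcy sink is implicit, and the
linearized pressure–velocity system is solved monolithically by sparse
LU. A step is accepted when the momentum and continuity residuals of
the *nonlinear* system at the current iterate fall below their
tolerances (default \(10^{-5}\), relative to the cancellation-free
row magnitudes \(|A||x| + |b|\), a measure that remains meaningful for
homogeneous right-hand sides). The initial iterate of a step is only
accepted without solving when its residual is identically zero, so
every accepted step reflects at least one solve. Velocity and pressure
updates can be under-relaxed; the defaults (1.0) suffice for the
laminar regimes here. Exceeding the outer-iteration budget raises a
classed error carrying the final residuals.

Two structural consequences are tested rather than assumed: summing
the continuity rows telescopes to the boundary flux integral, so
inflow and outflow balance to linear-solver precision at every
accepted step; and because a zero yield stress reproduces
\(\mu_\infty\) exactly and a unit porosity produces an exactly zero
sink, the Newtonian and uncoiled limits are bitwise identical to runs
with those features absent.

**Boundary conditions.** Velocity inlet (waveform-scaled profile),
no-slip walls, zero-traction outlet. Prescribing velocity at both ends
of an incompressible domain — a condition sometimes reported for such
simulations — is over-constrained unless the fluxes match identically,
so the outlet is the classical do-nothing condition here.
Traction (pressure) inlets and free-slip walls exist for the
verification problems (pressure-driven channels, porous slabs).

**Time stepping defaults.** \(\Delta t = 2\) ms (400 steps per cycle;
lands exactly on the 0.24 s and 0.54 s sampling phases), three cardiac
cycles from rest. The first cycles act as washout; all indices are
computed from the final cycle only. On the desk-scale fixture the
viscous time \(a^2/\pi^2\nu \approx 0.05\) s is much shorter than the
period, so the solution is periodic to high accuracy by cycle three —
the cycle-2 vs cycle-3 phase-matched L2 difference is far below the 5%
acceptance level; the check is retained as a guard for configurations
with slower transients.

## Wall indices

Wall shear is the tangential part of
\(\mu_{app}(\nabla u + \nabla u^T)\,n\) evaluated from the owning
element's P1 gradient on each wall facet — consistent with the
discretization, and verified against \(\tau_w = G a\) in
pressure-driven channel flow to 2%. Over the stored final cycle
(every step),
\[
\mathrm{TAWSS} = \frac1T\int \lVert\tau\rVert\,dt, \qquad
\mathrm{OSI} = \frac12\Bigl(1 -
\frac{\lVert\int\tau\,dt\rVert}{\int\lVert\tau\rVert\,dt}\Bigr)
\in [0, 0.5],
\]
by trapezoidal quadrature; an identically zero series (stagnant facet)
has OSI defined as 0 and is flagged. Region aggregates over
`WALL_SAC` / `WALL_VESSEL` are the maximum and the facet-length-
weighted average (the 2D surrogate of area weighting). The whole-cycle
integral definition of OSI is used throughout; instantaneous
end-of-cycle variants are not computed. Wall pressure statistics are
taken at the exact phase snapshots.

## Verification strategy

Because the quantities the method exists for have no desk-scale ground
truth on a patient geometry, verification is against closed forms:

- **Newtonian channel** (pressure-difference driven): wall shear
  \(G a\) and centerline \(G a^2/2\mu\) to 2%.
- **Casson channel**: the analytic plug profile (plug half-width
  \(\tau_y/G\)) imposed at the inlet persists mid-channel to 2% L2,
  sustained by a pressure gradient equal to \(G\) to 2%. Driving this
  case by boundary tractions instead is ill-conditioned under
  regularization: the plug viscosity (\(\sim 26\) Pa s at the
  \(10^{-3}\,\mathrm{s^{-1}}\) shear floor) couples into the inlet
  normal traction and shifts the effective gradient, which is a
  property of the regularized continuous problem, not of the
  discretization.
- **Darcy slab**: a fully porous channel with slip walls reproduces
  \(\Delta p = \mu U L / k\) to machine precision (the exact solution
  lies in the FE space).
- **Quadrature oracles** for OSI/TAWSS at \(10^5\) samples, brute-force
  oracles for aggregation and the shear-rate invariant, and round-trip
  oracles for mesh and checkpoint I/O.

The regularization floor \(\dot\gamma_{\min} = 10^{-3}\,\mathrm{s^{-1}}\)
bounds the plug viscosity; it is monotone and simpler than a
Papanastasiou exponential, and stagnant-zone WSS is near zero anyway.

## Numerical and fixture choices

The test fixture is the idealized geometry at 0.7 mm resolution on a
16 mm vessel with the sac at mid-length (about 350 triangles), chosen
so that a full three-cycle run takes well under a minute and the full
3 hematocrit × 3 porosity sweep stays desk-scale. At this resolution
absolute sac WSS is under-resolved — the refinement study shows the
asymptotic regime of the scheme starting near 0.5 mm elements, which
is where the grid-convergence harness operates (element sizes
0.55/0.42/0.32 mm, where successive change percentages decrease).
The channel verification problems use 0.1 mm elements with five
boundary-layer rows so the wall-shear extraction meets its 2% contract.

Degenerate inputs are rejected by name (negative lengths, neck wider
than dome, overpacked coils, non-positive porosities, time steps that
do not land on the cycle phases); all-zero shear histories, empty wall
regions and missing phase snapshots raise explicit errors rather than
NaNs.

## Known limitations

- 2D idealization: absolute Pa/OSI magnitudes are not comparable to 3D
  patient geometries; only within-pipeline comparisons are meaningful.
- The hematocrit correlation is a literature default, not a fit to the
  source study's (unpublished) coefficients.
- The porosity–permeability relation is a two-point interpolation;
  outside roughly [0.7, 0.9] it is extrapolation, clamped positive.
- No fluid–structure interaction, no thrombosis kinetics in the coil
  pack, no turbulence model (peak Reynolds number here is a few
  hundred; the flow is laminar).
- OSI on the uncoiled 2D fixture is essentially zero everywhere (the
  shear direction never reverses in a planar channel-plus-bulge at
  these parameters); the coiled cases do develop nonzero sac OSI,
  which is what the porosity trend report relies on.
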