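---
title: "Modelling spatially coordinated apoptosis execution by reaction-diffusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling spatially coordinated apoptosis execution by reaction-diffusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question the model addresses

During intrinsic apoptosis, mitochondrial outer membrane permeabilisation
(MOMP) can sweep across a cell as a slow wave (about 0.1 um/s), so
cytochrome-c and Smac reach the cytosol at one end of the cell minutes
before the other end. The execution machinery downstream — apoptosome
formation, caspase-9, effector caspases-3/-7, and their inhibitor XIAP —
consists of freely diffusing cytosolic proteins. `apoptowave` asks a
quantitative question: does protein diffusion erase this initial spatial
anisotropy before effector caspases commit the cell, or does apoptosis
execute as a travelling wave?

The cell is modelled as a 1-D segment of length $L = 30\,\mu m$ (a typical
HeLa cell). Every species $n$ obeys

$$\frac{\partial c_n}{\partial t} =
  D_n \frac{\partial^2 c_n}{\partial x^2} + R_n(c) + I_n(x, t),
  \qquad \left.\frac{\partial c_n}{\partial x}\right|_{x=0,L} = 0,$$

with mass-action reaction velocities $R_n$, zero-flux boundaries (the
plasma membrane), and MOMP inputs $I_n$ described below.

## Diffusivities

Diffusion coefficients derive from molecular mass via Stokes–Einstein
scaling anchored at cytosolic GFP:

$$D_n = D_{\mathrm{GFP}} \left(\frac{M_{\mathrm{GFP}}}{M_n}\right)^{1/3},
  \qquad D_{\mathrm{GFP}} = 24\ \mu m^2 s^{-1},\ M_{\mathrm{GFP}} = 27\ kDa.$$

The cube-root law is the hydrodynamic radius of a globular protein; it
makes a 216 kDa complex exactly half as mobile as GFP and the ~700 kDa
apoptosome about a third (8.1 um²/s). Because the GFP reference was
measured *inside* cells, baseline macromolecular crowding is folded into
the anchor; deviations for very large complexes are explored separately
through the immobilisation variant rather than through the scaling law.

## MOMP inputs

MOMP is not modelled mechanistically. Two pseudo-reactions deliver
(i) apoptosome-bound procaspase-9 (the cytochrome-c limb, capped by the
available procaspase-9/Apaf-1) and (ii) cytosolic Smac. Each follows a
first-order saturation $C_{max}(1 - e^{-k(t - t_{on}(x))})$ with a
location-dependent onset $t_{on}(x) = (x - x_0)/v_{wave}$. With
$v_{wave} = 0.1\,\mu m/s$ and $x_0 = 0$, the far end of a 30 um cell is
triggered exactly 5 min after the near end. Smac release
($k = 0.007\,s^{-1}$) is slower than apoptosome formation
($k = 0.015\,s^{-1}$), preserving the experimentally observed ordering of
the two processes.

**Onset smoothing.** The hard onset switch makes the right-hand side
non-smooth at one instant per grid node — 300 derivative kinks during the
wave transit — which forces an adaptive stiff integrator into ~30 ms
steps and inflates run times ~60-fold. The package therefore mollifies
the ramp with a softplus, $s(u) = \tau \log(1 + e^{u/\tau})$ with
$\tau = 1\,s$ by default, making the input $C^\infty$ while confining the
deviation from the ideal saturation curve to a ±3 s window around onset
(≤ 0.3 % of $C_{max}$ before onset). $\tau = 0$ recovers the exact sharp
contract and is used in the unit tests of the input functions. A side
effect worth knowing: at the origin the pre-onset part of the mollified
ramp is truncated (integration starts at $t = 0$), which shifts
no-diffusion delay read-outs by ~1 s — well inside every tolerance used
here.

## The reconstructed reaction network

The published tables behind the original parameterisation are not part of
the text this package was built from, so the default model file
(`inst/extdata/hela_reconstructed_model.yaml`) is an explicit
*reconstruction*: the topology follows the documented chemistry —

* apoptosome-bound procaspase-9 autoprocesses to its p35/p12 form and
  activates procaspases-3 and -7;
* active caspase-3 processes caspase-9 to p35/p10 (positive feedback; the
  p35/p10 form escapes XIAP) and autoprocesses procaspase-3;
* XIAP binds and inhibits caspase-9 (p35/p12), caspase-3 and caspase-7;
  caspase-3 cleaves XIAP into BIR1-2 and BIR3-RING fragments which retain
  their binding roles;
* Smac neutralises XIAP and both fragments;
* XIAP-bound caspases are ubiquitinated and degraded (the complex decays
  as a unit); effector-caspase activity shuts protein synthesis and
  degradation down in proportion to the cleaved-substrate fraction;
* an inert reporter substrate pair (uncleaved/cleaved) is the model
  output —

while concentrations and rate constants are literature-typical values
(XIAP 0.12 uM below the Smac amplitude 0.35 uM; procaspase-3 0.2 uM;
kon ~3–7 uM⁻¹s⁻¹ for inhibitor binding; see the model file for every
number). Calibration used only whole-cell phenomenology: execution
completes within minutes of MOMP, and the spatial behaviour below. Two
choices deserve comment because the qualitative spatial results depend on
them:

* **XIAP below Smac, degradation consumes the complex.** If XIAP is
  stoichiometrically dominant (or recycled from degraded complexes), the
  not-yet-triggered part of the cell acts as a long-lived sink for active
  caspase and Smac exported from the triggered end. Late-triggered
  regions then fire *faster* after their onset than early ones (the cell
  is globally "preconditioned"), and end-to-end delays at intermediate
  diffusivity impairment turn negative — the far end crosses thresholds
  first, which is not what is observed.
* **Weak caspase-3 autoprocessing.** Strong autocatalysis turns the
  system into an excitable medium supporting a trigger wave whose front
  speed grows as $\sqrt{D\,k}$; accelerating the kinetics then *speeds
  up* spatial propagation and reduces delays at strong impairment,
  inverting the reported effect of crowding-accelerated kinetics. The
  default keeps autoprocessing weak (0.05 uM⁻¹s⁻¹) relative to
  apoptosome-driven activation (0.5 uM⁻¹s⁻¹), an input-driven rather
  than ignition-driven regime. A residue of the trigger-wave effect is
  still visible in the onset (1 %) read-out of the 10× kinetics variant
  at 100-fold impairment, where its delta to reference is slightly
  negative; directionality claims are therefore asserted at the scales
  where they are robust (10-fold impairment for both thresholds,
  100-fold for half-maximal cleavage).

The XIAP synthesis rate is tied to turnover so that the pre-onset state
is stationary ($k_{syn} = k_{turn}\,[\mathrm{XIAP}]_0$); otherwise nodes
triggered later start from drifted initial conditions and the
no-diffusion end-to-end delay no longer equals the input delay.

## Numerics

Method of lines: 300 nodes over 30 um (0.1 um resolution) with a
conservative flux-form second difference and zero-flux boundaries. The
node-summed diffusion rate is exactly zero for any field; the price is
that the truncation error of the boundary closure sits in the two
boundary nodes (the interior stencil is second order). Grid-doubling
changes half-max crossing times by well under 1 %.

Time integration uses `deSolve::ode.1D` with `lsodes` (sparse-Jacobian
BDF) and a compiled right-hand side; defaults rtol = 1e-6,
atol = 1e-9 uM, 1 s save interval, all config-exposed. Delay metrics
interpolate linearly between saves; tightening rtol tenfold moves them by
less than a second. Concentrations are clipped at zero inside the RHS;
saved values never undershoot below −1e-9 uM. The local (single-point)
ODE model uses `lsoda` and doubles as the no-diffusion oracle: with all
$D_n = 0$ the spatial solution at node $x$ must equal the local solution
time-shifted by $t_{on}(x)$, to integration tolerance.

Read-outs: substrate cleavage fraction per node; "onset" = 1 % and
"half-maximal" = 50 % crossings (linearly interpolated, missing if never
reached); the end-to-end delay is far-end minus near-end crossing time.
Synchrony is judged against a 10 s tolerance — a reported choice, not a
hard-coded one. Diffusivity impairment divides every $D_n$ by a scale
factor; the sweep grid is the decade series 1…10⁴ plus the exact $D = 0$
case.

## What the model run shows

At reference diffusivities the near- and far-end cleavage traces
superimpose (half-max delay ≈ 0.01 s against a 300 s input stagger);
without diffusion the full 300 s stagger survives to the output. Between
those poles the delay grows monotonically with impairment — noticeable
around 25–100-fold, close to the no-diffusion limit at 10⁴-fold. Caspase
feedback knockouts slow overall execution but change the delays by only a
few seconds (longer lag gives diffusion more time to mix); 10× faster
kinetics and apoptosome immobilisation increase the delays at
intermediate impairment, and their combination exceeds either alone.

## 1-D versus 3-D

Collapsing a cell to one dimension deserves an error estimate. The
package compares pure diffusion of one tracer in a slab (input pulse at
the left boundary) against a sphere with a synchronous surface input
(radially symmetric finite-volume solver, validated to 0.001 % against
the closed-form eigenfunction series for a clamped surface
concentration). With matched total amount, travel distance (L = R =
30 um), D = 24 um²/s and the slow Smac-like delivery rate (0.007 s⁻¹),
the maximum per-depth relative discrepancy in half-equilibrium arrival
times is ~11 %, concentrated in the surface shell — small in the sense
that matters here, since execution takes minutes. This conclusion is
regime-dependent and worth stating plainly: for sharp input pulses
(delivery ≳ 0.015 s⁻¹ at these scales) the surface-shell discrepancy
grows to 25 % and beyond, so the 1-D reduction is adequate for
slow-release MOMP scenarios, not for fast localised bursts.

## Problem sizes and determinism

Everything is deterministic; re-running any scenario from its persisted
configuration reproduces every exported number bit-for-bit. The shipped
verification suite runs the full 300-node grid for the reference
synchrony check and 150 nodes for sweeps and variant comparisons (the
delay metrics move by <1 % between 150 and 300 nodes); no-diffusion
equivalence checks use 61 nodes, where results are node-count-independent
because the nodes decouple. These sizes are the package's own choices
for routine verification; all entry points accept the full grid.

## Known limitations

* One spatial dimension with a single wave origin; no 3-D anisotropic
  geometry (the slab/sphere check bounds only the radially symmetric
  error).
* MOMP is an imposed input: no Bax/Bak pore mechanics, no feedback from
  execution onto release, and strictly deterministic onset times.
* The parameter set is a labelled reconstruction; absolute times (e.g.
  time from MOMP to half-max cleavage) should be read as
  order-of-magnitude, while the *relative* spatial conclusions are
  robust across the calibration ranges explored.
* Mass-action kinetics throughout; no explicit crowding, binding-site
  saturation, or stochasticity (molecule numbers in a 30 um cell at
  0.1 uM are in the tens of thousands, so deterministic kinetics are
  defensible).
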