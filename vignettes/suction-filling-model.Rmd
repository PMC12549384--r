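---
title: "Modelling suction pressure and filling yield in tablet-press die filling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling suction pressure and filling yield in tablet-press die filling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(suctionfill)
```

## The process and the model

During die filling on a rotary tablet press, the lower punch is pulled
down beneath the powder bed of the feed frame. The growing cavity rarefies
the enclosed air and the resulting differential pressure
$\Delta p = p_\mathrm{atm} - p$ draws air — and with it powder — through
the bed into the die. The package models the *air* side of this process:
an isothermal ideal-gas balance over the cavity volume
$V(t) = A_\mathrm{die}\,(h_0 + h(t))$, replenished by Darcy flow through a
powder bed of permeability $K$ and height $L$,

$$\frac{dp}{dt} \;=\; \frac{c\,(p_\mathrm{atm} - p) \;-\; p\,v(t)}{h_0 + h(t)},
\qquad c = \frac{R\,T\,K\,\rho_\mathrm{air}}{\eta_\mathrm{air}\,L\,M_\mathrm{air}},$$

where $v(t)$ is the punch velocity, $h(t)$ its integral (downward
displacement), and $h_0$ the initial cavity height left by the fill cam.
The assumptions are: ideal gas, isothermal process, uniform bed height,
no powder entering the die, and no leakage through the punch–die gap.
These are strong idealizations — the model is a mechanistic lens on how
machine geometry, cam geometry and permeability interact, not a predictor
of absolute in-die conditions (powder motion, the dominant omission, is
deliberately out of scope).

Two limits anchor the model analytically and serve as test oracles:

* **Constant punch velocity** (rotary press): the pressure relaxes to the
  fixed point $\Delta p^\ast = p_\mathrm{atm}\,v/(c+v)$, where Darcy
  inflow balances volume expansion.
* **Impermeable bed** ($K = 0$, stearate cam): no inflow, so the gas obeys
  Boyle's law, $p\,(h_0 + h) = \text{const}$.

With the default ideal-gas-consistent air density, $c$ collapses to
$K\,p_\mathrm{atm}/(\eta_\mathrm{air} L)$ — a velocity scale. A punch
moving much slower than $c$ barely disturbs the pressure; at $v \sim c$
the suction pressure reaches half its ceiling $p_\mathrm{atm}$.

## Parameters and defaults

| Parameter | Default | Unit | Rationale |
|---|---|---|---|
| $T$ | 293.15 | K | ambient; all air properties overridable |
| $p_\mathrm{atm}$ | 101325 | Pa | standard atmosphere |
| $M_\mathrm{air}$ | 0.02896 | kg/mol | dry air |
| $\eta_\mathrm{air}$ | 1.8e-5 | Pa·s | dry air at ambient T |
| $\rho_\mathrm{air}$ | $p_\mathrm{atm} M/(RT) \approx 1.20$ | kg/m³ | ideal-gas consistent; removes a free parameter |
| $L$ | 6 mm (rotary) / 11 mm (simulator) | m | feed-frame spoke height of each machine |
| die radius | 4.5 | mm | 9 mm round EU-D tooling |
| filling / dosing height | 16 / 15.5 | mm | tooling setup |
| stearate pre-pull $h_s$ | 4.7 | mm | cam geometry; conventional cam has $h_s = 0$ |
| $\theta_\mathrm{ppd}$ | 72 | degrees | **assumption** — the pull-down sector is machine-specific and not generally tabulated; every kinematic quantity is linear in it, so results should be read alongside this value |
| stationary-window threshold | 0.95 | of max v | plateau detection in report analysis; a fractional threshold is robust to noise |
| $t_\mathrm{start}$ | 1e-6 | s | avoids the $h_0 = 0$ singularity; applied to both cams for uniformity |
| rtol / atol | 1e-6 / 1e-8 | — | working tolerances; verified against 1e-12/1e-14 below |

Material constants (densities in g/cm³ as conventionally tabulated,
converted to SI internally; $K$ in m²) live in the bundled
`materials.csv` fixture and reproduce the tabulated compressibility
indices of the three excipients within the rounding of their inputs.

## Punch kinematics

On the rotary press the turret guides the punch down a linear cam slope:
the velocity is constant at $v_\mathrm{ppd} = h_\mathrm{ppd}/t_\mathrm{ppd}$
with $t_\mathrm{ppd} = \theta_\mathrm{ppd}/(360°\, n_t)$. On the
compaction simulator the punch starts at rest, accelerates to a
stationary velocity and decelerates to rest at the target filling height.
`build_simulator_profile()` constructs this three-phase profile with
second-degree polynomial ramps constrained by $v(0)=0$, continuity,
$v(\mathrm{end})=0$ and $\int v\,dt = h_\mathrm{ppd}$. Given the phase
split, those constraints leave one degree of freedom per ramp, fixed by
requiring both ramps to have the same fill factor
$\gamma = \int_\mathrm{ramp} v\,dt / (v_s\,t_\mathrm{ramp})$; a monotone
quadratic ramp exists iff $\gamma \in [1/3, 2/3]$, which bounds the
feasible stationary velocities and is enforced with an informative error.
The default stationary velocity is 1.5× the mean pull-down velocity with
0.3/0.3 phase fractions — a single, fixed choice representing the
simulator's characteristically elevated plateau velocities (its exact
servo trajectory is machine-tuned and not publicly tabulated); the
profile-averaged velocity always equals $h_\mathrm{ppd}/t_\mathrm{ppd}$
by construction.

Report analysis mirrors instrument practice: the stationary window is the
maximal contiguous run of samples at ≥95% of peak velocity; acceleration
and deceleration are OLS slopes of velocity vs. time on the segments
before and after the window; per-report plateau means are pooled across
reports with inverse-variance weights. For noiseless traces a threshold
of exactly the plateau recovers the generator value to machine precision;
the 0.95 default trades a small (<0.2%) ramp-inclusion bias for noise
robustness.

## Numerical solution

The ODE is stiff near $t = 0$ for the conventional cam: the local rate
$(c+v)/(h_0+h)$ diverges as the cavity height vanishes. It is solved with
the L-stable implicit Runge-Kutta Radau IIA method of order 5
(`deSolve::radau`), from $p(t_\mathrm{start}) = p_\mathrm{atm}$ at
$t_\mathrm{start} = 10^{-6}$ s to the end of the pull-down, with 300
evenly spaced output points (uniform spacing is the simplest reading of a
"300 points spanning the filling time" output contract). Post-solve
checks enforce $0 \le \Delta p \le p_\mathrm{atm}$.

Verification is three-fold:

1. **Convergence**: the working tolerances (1e-6/1e-8) reproduce the peak
   $\Delta p$ of a 1e-12/1e-14 reference within 0.003% across all 24
   material × machine × cam × turret-speed scenarios (target ≤ 0.1%).
2. **Independent oracle**: a forward-Euler integrator at a nominal 1e-6 s
   step agrees within 0.5% in peak $\Delta p$. Near $t=0$ on conventional
   cams a literal fixed step is outside the explicit stability region
   (the local rate exceeds $10^6\,\mathrm{s^{-1}}$), so the oracle caps
   its step at half the local stability limit there; for stearate cams
   the cap never binds and the scheme is the literal fixed-step Euler.
3. **Analytic limits**: fixed-point convergence for constant $v$, and
   Boyle's-law conservation for $K = 0$. Because integration starts at
   $t_\mathrm{start}$, the conserved quantity is anchored there:
   $p\,(h_0+h) = p_\mathrm{atm}(h_0 + h(t_\mathrm{start}))$, which
   differs from $p_\mathrm{atm} h_0$ by the fixed relative offset
   $v\,t_\mathrm{start}/h_0 \approx 10^{-5}$ — an artefact of the start
   offset, not solver error.

Degenerate inputs are rejected rather than repaired: zero dosing height,
non-monotone particle sizes, $\rho_b > \rho_t$, infeasible profile
constraints, and empty stationary windows all raise errors.

## The synthetic-data generator

No raw punch reports or tablet weights are published for this process, so
the generator provides controllable stand-ins with known ground truth.
It emulates two data streams:

* **Punch reports**: the scenario's velocity profile sampled at 2000 Hz,
  white Gaussian noise (default sd = 1% of the plateau) on the velocity
  channel, noiseless integrated displacement — matching the smooth
  instrument displacement traces. Autocorrelated noise and servo
  artefacts are *not* emulated.
* **Tablet weights**: Gaussian draws around $\mu_\phi \times$ theoretical
  mass, where $\mu_\phi = \phi_0\, s(\Delta p_\mathrm{max})\, g(u)$ with
  exponential-saturation links
  $s = 1 - a_s e^{-\Delta p/\Delta p_\mathrm{ref}}$ and
  $g = 1 - a_g e^{-u/u_\mathrm{ref}}$ ($u$ = paddle revolutions during
  the fill). These links are synthetic: they encode the qualitative
  phenomenology (yield limited by suction intensity and powder supply,
  saturating in both) with interpretable parameters, nothing more.
  Bridging, jamming, in-die densification dynamics and feed-frame
  residence-time structure are not modelled.

Passing recovery tests therefore demonstrates that the *analysis stages*
are unbiased and correctly scaled at realistic noise levels and sample
sizes (10 reports, 10–20 tablets per cell) — not that real die filling
follows the generator's links.

All generators are deterministic given their seed, restore the caller's
RNG state, and write byte-identical CSVs on repeated calls.

## Problem sizes

The bundled analyses and tests use the study's native sizes throughout:
5 × 7 process grids per scenario, 10 reports per turret speed at 2000 Hz
(0.2–0.6 s traces), 300-point pressure curves, and the full 24-scenario
convergence sweep — each completing in seconds, so nothing is
down-scaled.

## Known limitations

* The pull-down sector $\theta_\mathrm{ppd}$ is an assumption (72°);
  absolute times and velocities scale linearly with it, ratios and
  orderings do not.
* The pressure model ignores powder motion; measured suction pressures in
  a filled, flowing system will differ, and the model's value is
  comparative (materials, cams, machines) rather than absolute.
* $\rho_\mathrm{air}$ is held at its ambient value in the Darcy inflow
  term, consistent with treating $c$ as a constant; at
  $\Delta p \gtrsim 20$ kPa (cohesive materials at high punch speed) the
  incurred density error reaches ~20% of the inflow term.
* The yield pipeline reports weight RSD as the dispersion measure; it
  does not implement pharmacopoeial acceptance-value computations.
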