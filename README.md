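# suctionfill

Physics-based modelling of **die filling in tableting** — the process step
that sets tablet weight and its variability. When the lower punch of a
tablet press is pulled down directly beneath the powder bed of the feed
frame ("suction filling"), it rarefies the air in the growing die cavity
and the resulting differential pressure Δp actively draws powder into the
die. How strong that suction is depends on the punch kinematics (machine
and fill-cam geometry) and on the air permeability of the powder bed.

The package is aimed at pharmaceutical process engineers comparing die
filling across machine scales (laboratory rotary press vs. compaction
simulator) and fill-cam geometries (conventional vs. stearate cams). It
provides:

* **Powder characterization** — flow function coefficient
  `ffc = σ1/σ0` with Jenike classification, Carr compressibility index
  `CI = (ρt − ρb)/ρt · 100`, and Darcy-law air permeability
  `Q = K·A/(η·L) · Δp` with its inversion.
* **Punch kinematics** — pull-down time `t_ppd = θ_ppd/(360°·nt)` and
  linear velocity `v_ppd = h_ppd/t_ppd`; constant-velocity rotary
  profiles and three-phase (acceleration / stationary / deceleration)
  simulator profiles with quadratic ramps; analysis of 2000 Hz punch
  instrumentation reports with inverse-variance weighted pooling
  (`μ_w = Σ(μᵢ/σᵢ²)/Σ(1/σᵢ²)`, `σ_w = (Σ 1/σᵢ²)^(-1/2)`).
* **The suction-pressure ODE** — an isothermal ideal-gas balance over the
  die cavity with Darcy inflow through the powder bed:

  ```
  dp/dt = [ c·(patm − p) − p·v(t) ] / (h0 + h(t)),    c = R·T·K·ρair / (η·L·Mair)
  ```

  solved with the implicit Runge-Kutta Radau IIA (order 5) method
  (`deSolve::radau`), 300 output points spanning the filling time,
  starting at t = 10⁻⁶ s to avoid the h0 = 0 singularity of the
  conventional cam. For constant punch velocity the solution relaxes to
  the stationary value `Δp* = patm·v/(c + v)`.
* **Filling-yield analysis** — `ϕ = mt / (π·r_die²·h_d·ρb)` per tablet,
  with grid summaries (mean ϕ, weight RSD, overfill flags) over
  turret-speed × paddle-speed designs.
* **A synthetic-data generator** — punch reports and tablet-weight
  datasets with known ground truth, for end-to-end validation of the
  analysis stages.

## Worked example

```r
library(suctionfill)

mats <- fixture_materials()         # DCP, MCC, LAC with tabulated constants
compressibility_index(mats$LAC$rho_bulk, mats$LAC$rho_tapped)
#> [1] 32.65306                      # percent: a cohesive powder

spec <- pressure_model_spec(mats$LAC, fill_cam("stearate"),
                            machine_config("compaction_simulator", 20))
curve <- solve_pressure(spec)
curve
#> Pressure curve: LAC, stearate cam, compaction_simulator, nt = 20/min
#>   300 points over [1e-06, 0.6] s
#>   max delta_p = 9077 Pa (rise time 0.1886 s)
```

The 9.1 kPa maximum suction pressure and the ~0.19 s rise time show the
stearate cam's initial 4.7 mm air pocket buffering the buildup for the
low-permeability lactose. With a conventional cam at the same settings
the model gives a faster rise to a higher Δp; for the highly permeable
DCP both values collapse by roughly an order of magnitude.

The `analysis/` directory holds the full workflow as numbered scripts
(run from the repository root, outputs under `results/`):
`01_characterize.R`, `02_kinematics.R`, `03_pressure_curves.R`,
`04_convergence.R`, `05_yield_study.R`.

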