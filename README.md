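# laawash

Residence-time analysis of blood-borne-particle washout from the left
atrial appendage (LAA), at desk scale.

In atrial fibrillation the LAA — a blind pouch off the left atrium — is
the principal site of thrombus formation, and the mechanistic risk
marker is blood stasis: how long particles reside inside the appendage.
`laawash` quantifies stasis the way patient-scale CFD studies do, but on
idealized 2D atrium-plus-pouch geometries and a synthetic cohort so a
full study runs in minutes on one CPU:

1. **Hemodynamics** — laminar incompressible generalized-Newtonian flow
   on a masked staggered grid (projection method), with either a
   Newtonian viscosity or the Quemada hematocrit-dependent
   shear-thinning law
   μₐ = μₚ(1 − ½·k·Hct)⁻², k = (k₀ + k∞√(γ̇/γ̇c)) / (1 + √(γ̇/γ̇c)).
2. **Washout** — an Eulerian passive tracer initialized to 1 inside the
   appendage is advected out (conservative donor-cell scheme); the
   appendage-averaged concentration C(t) is recorded.
3. **RTD indices** — C(t) is fitted to a triple exponential plus
   asymptote, C(t) = C∞ + Σᵢ aᵢ·exp(−t/τᵢ); the residence-time
   distribution E(t) = Σᵢ(aᵢ/τᵢ)e^(−t/τᵢ)/Σᵢaᵢ gives the mean residence
   time t_m = Σaᵢτᵢ/Σaᵢ, and C∞ is the fraction that never leaves.
4. **Cohort statistics** — effects-coded fixed-subject OLS regressions
   of t_m and C∞ on cardiac output and pulmonary-vein pulsatility
   indices (SysP, RevP), on hematocrit × rheology factorials, and
   Spearman rank-stability analysis of simulation-length truncation.

It is intended for researchers in cardiovascular flow modeling who want
a fast, fully reproducible sandbox for the *confounders* of LAA
residence indices — inflow pulsatility vs. cardiac output, blood
rheology and hematocrit, and simulation length — with every numerical
ingredient tested against analytic oracles.

## Worked example

Solve a steady inflow of 4.4 L/min over the default 6 mm pouch with
Quemada blood at 45.5% hematocrit, wash the tracer out for 300 s, and
fit the RTD model:

```r
library(laawash)
grid <- build_geometry(geometry_spec(pouch_depth = 0.006))
grid
#> <laa_grid> 98x22 cells, h = 0.0008333 m
#>   fluid: 1194  appendage: 42  inlets: 4
rheo <- rheology_params("quemada", hct = 0.455)
flow <- solve_flow(grid, rheo, 4.4, solver_config(tol_velocity = 1e-7))
flow
#> <flow_solution> mode = steady  dt = 0.00189 s, steps = 800
#>   max divergence: 8.06e-14 1/s
series <- run_washout(grid, flow, t_max = 300)
series
#> <concentration_series> 1973 samples over 300 s; C_LAA(end) = 0.001126
fit <- fit_concentration(series)
fit
#> <rtd_fit> C(t) = 0 + 0.0774 exp(-t/0.4328) + 0.427 exp(-t/25.12) + 0.5001 exp(-t/50.6)
#>   t_m = 35.902 s,  C_inf = 0,  rms = 0.00139
```

Reading: a fast mode (τ ≈ 0.4 s, 8% of the tracer) clears the
neck region almost immediately; the pouch recirculation drains the rest
on 25–50 s time scales. The mean
residence time of 36 s is the first moment of the fitted RTD; C∞ = 0
says nothing is permanently trapped at this inflow. Dropping the
cardiac output or deepening the pouch raises t_m; switching to the
shear-matched Newtonian comparator
(`rheology_params("newtonian", mu = equivalent_newtonian_viscosity(0.455))`)
lowers it.

Cohort-level studies have one-call drivers:

```r
cfg <- experiment_config()       # 8 synthetic subjects, seed 1
sweep <- run_waveform_sweep(config = cfg)      # 3 CO x 3 waveform types
sweep$reg_tm                     # effects-coded OLS: t_m ~ CO + SysP + RevP
```

`inst/scripts/laawash-cli.R` exposes `sweep`, `factorial`, `truncation`
and `all` as shell subcommands.

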