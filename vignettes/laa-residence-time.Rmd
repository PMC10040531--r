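---
title: "Quantifying blood stasis in the left atrial appendage: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying blood stasis in the left atrial appendage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(laawash)
```

## The problem

In atrial fibrillation the left atrial appendage (LAA) — a blind-ended
pouch off the left atrium — loses its contractile emptying and becomes
the dominant site of intracardiac thrombus formation. A natural
mechanistic index of thrombogenic risk is how long blood-borne particles
linger inside the appendage. `laawash` quantifies this with a
residence-time-distribution (RTD) analysis of an Eulerian tracer: the
appendage is filled with a passive scalar at concentration 1, the flow
washes it out, and the recorded appendage-averaged concentration
\(C(t)\) is summarized by two indices — the mean residence time
\(t_m\) of the particles that leave, and the asymptotic concentration
\(C_\infty\), the fraction that never does.

The package is a desk-scale laboratory for the *confounders* of those
indices: how they respond to pulmonary-vein (PV) inflow pulsatility
versus mean cardiac output, to hematocrit and the choice of blood
rheology model, and to the length of the simulation from which they are
fitted. Patient anatomies are replaced by idealized two-dimensional
atrium-plus-pouch geometries and a synthetic cohort, so every study runs
in minutes on one CPU while the numerical and statistical machinery is
the same as at clinical scale.

## Governing equations and rheology

The solver integrates the incompressible Navier–Stokes equations with a
generalized-Newtonian stress: the momentum balance
\(\rho\,Du_i/Dt = \partial \tau_{ij}/\partial x_j\) with
\(\tau_{ij} = -p\,\delta_{ij} + 2\mu_a e_{ij}\) and strain-rate tensor
\(e_{ij} = \tfrac12(\partial_j u_i + \partial_i u_j)\). Because the flow
is incompressible the bulk term \(\tfrac23\mu\nabla\!\cdot\!u\) of the
full constitutive law vanishes and is not carried. The scalar shear-rate
magnitude \(\dot\gamma = \sqrt{2\,e_{ij}e_{ij}}\) drives the apparent
viscosity.

Blood is modeled either as Newtonian (\(\mu = 3.71\times10^{-3}\) Pa s
by default) or with the Quemada law,
\[
\mu_a \;=\; \mu_p\bigl(1 - \tfrac12 k\,\mathrm{Hct}\bigr)^{-2},
\qquad
k \;=\; \frac{k_0 + k_\infty\sqrt{\dot\gamma/\dot\gamma_c}}
             {1 + \sqrt{\dot\gamma/\dot\gamma_c}},
\]
with plasma viscosity \(\mu_p = 1.23\times10^{-3}\) Pa s and
\(k_0, k_\infty, \dot\gamma_c\) exponentials of cubic polynomials in
hematocrit (`quemada_coefficients()`). One subtlety of these fitted
polynomials: \(k_0\) grows steeply toward low hematocrit, and
\(\tfrac12 k_0\,\mathrm{Hct}\) crosses 1 in a band around
Hct ≈ 0.13–0.17, where the zero-shear viscosity diverges (a gel-like
limit). The apparent viscosity is therefore evaluated at
\(\max(\dot\gamma, \dot\gamma_{\min})\) with a low-shear cutoff
\(\dot\gamma_{\min} = 10^{-3}\,\mathrm{s^{-1}}\) — far below any
hemodynamically relevant shear (channel shear here is 1–20 s⁻¹) — which
keeps the law finite everywhere on \(\mathrm{Hct} \in [0, 0.65]\);
hematocrits that remain singular even at the cutoff are rejected at
construction. The square-root form of the
shear-rate ratio is the standard Quemada interpolation; evaluated at
\(\dot\gamma = 2000\,\mathrm{s^{-1}}\) it yields equivalent Newtonian
viscosities of 2.56, 3.72 and 5.43 mPa s at hematocrits of 27.4%, 45.5%
and 60.4% — the middle value also recovering the package's Newtonian
default to two significant figures, which is the internal consistency
check for the calibration. Note the sensitivity of this quantity:
reading the same three values off a viscosity–shear chart at two
significant figures gives 2.5/3.7/5.4, and the first of these differs
from the polynomial evaluation in its second digit (2.56 rounds to
2.6). The package always reports the polynomial value.

## Geometry, boundary conditions and the cardiac-output mapping

The atrium is a straight channel (height \(H = 1\) cm) with `n_inlets`
PV inlets on the upstream boundary and a wide-open outlet at the end of
a downstream extension that keeps outlet backflow away from the region
of interest. The appendage is a rectangular pouch (optionally tilted,
optionally two-lobed) hanging below the channel floor; the neck plane
\(y = 0\) defines LAA membership, a convention the package states
explicitly because patient-scale studies rarely define the ostium plane
computationally. Walls are rigid and no-slip; inlets carry a single
uniform velocity so the flow splits across inlets in proportion to their
widths; the outlet is zero-gradient at zero gauge pressure.

Physiologic cardiac output maps to inlet velocity by Reynolds matching:
\(\mathrm{Re} = \rho U H/\mu_{\mathrm{ref}} = 20 \times
\mathrm{CO}\,[\mathrm{L\,min^{-1}}]\), using the *fixed* reference
viscosity \(\mu_{\mathrm{ref}} = 3.71\times10^{-3}\) Pa s for every
rheology, so a rheology factorial changes only the constitutive law and
never the imposed inflow. The constant 20 keeps the toy domain laminar
(Re 38–136 across the cohort range) with practical time steps; the CO
*rank ordering* — the thing the regressions consume — is preserved
exactly by construction. This is far below atrial Reynolds numbers, and
is the main reason cohort-level *magnitudes* here are not comparable to
patient-scale values (see Limitations).

## Waveforms

Three PV waveform types are synthesized from raised-cosine lobes over
fixed phase fractions of the cycle (systole/diastole/reversal =
0.40/0.45/0.15 for the normal template, 0.35/0.45/0.20 for the AF
template). Template *shapes* are not treated as normative — only the
tabulated constraints are: the cycle mean equals the cardiac output, and
the normalized systolic peak (SysP) and reversal peak (RevP) equal the
tabulated template values at CO = 3.3/4.4/5.5 L/min, interpolated
linearly in between. For the steady waveform both indices are reported
as 1, matching the tabulated convention for a zero-variance waveform
even though a constant positive flow has no reversal; that convention is
isolated in `pulsatility_indices()`. One non-normative consequence of
the constraint set: for the normal template the diastolic lobe must
carry most of the cycle mean, so its amplitude (≈ 2.8 × CO) exceeds the
systolic peak — the systolic-phase peak, which defines SysP, still
carries exactly SysP × CO.

## Discretization

The flow solver is a first-order projection method on a masked staggered
(MAC) grid: donor-cell upwind advection (first order only — at the
coarse desk grids a higher-order option changes little and complicates
the boundedness argument), implicit variable-viscosity diffusion solved
matrix-free by Jacobi-preconditioned conjugate gradients, an explicit
cross-stress term, and a pressure Poisson solve (warm-started
preconditioned CG, Dirichlet gauge in the outlet cells) driving the
post-projection divergence below `tol_div` (default \(10^{-8}\,
\mathrm{s^{-1}}\)). The apparent viscosity is evaluated from the
previous step's strain field (Picard lag), updating every cell at every
step. The time step defaults to the advective CFL limit (diffusion being
implicit) and is halved automatically, with the run restarted, if the
runtime CFL ceiling is hit. Steady solves march until the maximum
velocity change per step falls below `tol_velocity`
(\(10^{-8}\) m/s by default; the desk-scale studies use
\(10^{-7}\) m/s); pulsatile solves run `spin_up_cycles` cardiac cycles
(default 25, after the convention of starting tracer transport only once
the flow is periodic; the desk studies use 3, where the cycle-to-cycle
L2 residual is already below \(10^{-6}\) of the velocity scale) and then
record one cycle of snapshots.

Tracer transport is conservative donor-cell advection of a source-free
scalar with inlet concentration 0 and outflow-only outlet flux, run over
the frozen steady field or the cyclically replayed snapshot cycle. Two
properties are enforced to round-off and tested: mass balance
(\(M(0) = M(t) + \) cumulative boundary outflux) and boundedness
(\(-10^{-10} \le C \le 1 + 10^{-10}\)). Boundedness over
\(10^4\)-step horizons requires the replayed fields to be
divergence-free to much better than the flow solver's per-step
tolerance, so every field handed to the tracer receives one extra
projection converged to \(10^{-13}\,\mathrm{s^{-1}}\). There is no
molecular-diffusion term; the donor-cell scheme's numerical diffusion
(\(\sim u h/2\)) is a property of the discretization, characterized by
the tests rather than modeled.

## RTD fitting

The washout curve is fitted to
\(C(t) = C_\infty + \sum_{i=1}^3 a_i e^{-t/\tau_i}\) — fast, moderate
and slow washout phases plus an asymptote — by constrained nonlinear
least squares. The fit is deterministic: candidate \(\tau\) triplets
come from a log-spaced grid spanning \([10\,\Delta t_{\mathrm{sample}},
10\,\mathrm{window}]\); for each triplet the amplitudes and asymptote
solve a nonnegative linear least-squares problem (variable projection);
the best candidates are refined by bounded Levenberg–Marquardt in
\((a_i, \log\tau_i, C_\infty)\). The constraint
\(a_1+a_2+a_3+C_\infty = C(0)\) is a soft penalty (one
pseudo-observation), tolerating early-time discretization transients.
Time constants are reported in increasing order, with zero-amplitude
modes allowed, which resolves the exchange-symmetry degeneracy.

The RTD function is the negative derivative of the fitted curve
normalized by the washed-out fraction,
\(E(t) = \sum_i (a_i/\tau_i) e^{-t/\tau_i} / \sum_i a_i\), so
\(\int_0^\infty E\,dt = 1\) even when \(C_\infty > 0\) and
\(t_m = \sum a_i\tau_i / \sum a_i\) is finite and interpretable as the
mean over particles that leave. This normalization is the package's own
convention: without it, any permanently trapped tracer would make the
first moment diverge.

## The synthetic cohort and the three studies

`generate_cohort()` draws subjects with cardiac output 1.9–6.8 L/min,
heart rate 44–84 bpm and hematocrit 35–49% — the printed ranges of the
clinical population this design emulates — plus a subject-specific pouch
(depth 4–9 mm, neck 4–6 mm, bend 0–40°, one or occasionally two lobes)
standing in for patient-specific appendage morphology. Cardiac output is
drawn directly; `teichholz_cardiac_output()` is provided for cohorts
specified via ventricular diameters. Everything is bit-reproducible from
one integer seed.

The three studies (`run_waveform_sweep()`, `run_rheology_factorial()`,
`run_truncation_study()`) mirror the clinical-scale design: 9
waveform-by-CO settings per subject; {Newtonian at the equivalent
viscosity, Quemada} × three hematocrit levels (27.4/45.5/60.4%) at a
steady 4.4 L/min inflow; and prefix refits of one long washout per
subject on a geometric window ladder (the 625→30,000 s ladder of the
patient-scale study, expressed as fractions of the horizon), with
Spearman rank stability against the longest window. Outcomes feed
effects-coded fixed-subject OLS regressions (`fit_waveform_model()`,
`fit_rheology_model()`), with classical normal-theory standard errors
and no multiple-testing correction, and \(P < 0.05\) as the
significance threshold throughout.

## Problem sizes and numerical choices

The default desk conditions (all overridable in `experiment_config()`):
8 subjects; cell size \(h = H/12 \approx 0.83\) mm (the pouch neck is
resolved by at least 4 cells, the enforced minimum); outlet extension 3
cm in the cohort geometry (the standalone `geometry_spec()` default is
the more conservative 5 channel heights); washout horizon 300 s sampled
at `horizon/2000` (the truncation study samples faster so its shortest
window still holds ≥ 50 points). The horizon was set by the requirement
that it be long compared with the slowest steady-case residence times
(60–200 s on cohort geometries): fitting \(C_\infty\) together with a
slow mode from a window shorter than the slow time constant is
ill-posed, which is precisely the failure mode the truncation study
demonstrates on purpose for its shortest windows. The full suite of
three studies runs in roughly ten minutes on one CPU.

Degenerate inputs are rejected early with specific errors: necks
resolved by fewer than 4 cells, empty appendages, hematocrit above the
Quemada singularity \(\tfrac12 k_0(\mathrm{Hct})\,\mathrm{Hct} \ge 1\),
infeasible waveform constraint sets (negative diastolic amplitude),
windows with fewer than 50 samples, zero rank variance in the Spearman
correlation (flagged `NA` with a warning, not an error).

## What the synthetic studies do and do not show

The generator emulates the *structure* of a clinical cohort — ranges,
study design, observation counts, analysis pipeline — not its anatomy
or hemodynamic regime. Passing studies therefore demonstrate that the
machinery (solver, tracer, fit, statistics) behaves correctly and that
robust physical orderings survive the translation: residence time falls
steeply with cardiac output; the shear-thinning Quemada model retains
tracer longer than its shear-matched Newtonian comparator and its
residence times rise with hematocrit; subject rank ordering is stable
once the fit window reaches about two thirds of the horizon.

Two clinical-scale findings do *not* survive the 2D desk regime, and the
package reports them as they come out rather than adjusting conditions
until they match. First, pulsatility: with the pouch directly beneath a
rigid 2D channel, the systolic peak re-energizes the neck shear layer
every cycle and pulsatile inflow washes the pouch substantially faster
than steady inflow at the same mean — so the pulsatility indices carry
significant regression weight here, whereas in the 3D atrium they do
not. Second, the Newtonian arm of the rheology factorial: near the
Stokes regime of this toy (pouch Reynolds numbers of order ten), raising
the Newtonian viscosity *strengthens* the viscous coupling that drives
the pouch recirculation, so Newtonian residence time mildly decreases
with hematocrit instead of increasing. The Quemada arm, where the
low-shear pouch interior thickens dramatically with hematocrit, shows
the expected increase. Both effects are physically sensible in two
dimensions and are flagged wherever the corresponding qualitative checks
are asserted.

Other known limitations: rigid walls (no atrial reservoir function, no
wall motion), no mitral valve or ventricle, laminar flow only, pure
advection (no residence-time-activated rheology, no coagulation
biochemistry), first-order accuracy in space and time, and a
cardiac-period-to-washout-time ratio orders of magnitude larger than at
clinical scale, which inflates the influence of anything periodic.

## Reproducing the studies

```{r example}
cfg <- experiment_config(
  solver = solver_config(spin_up_cycles = 3L, tol_velocity = 1e-7))
cohort <- generate_cohort(cfg$n_subjects, cfg$seed, cfg$ranges)
sweep <- run_waveform_sweep(cohort, cfg)
sweep$reg_tm          # effects-coded OLS of t_m on CO, SysP, RevP
factorial <- run_rheology_factorial(cohort, cfg)
truncation <- run_truncation_study(cohort, cfg)
```

`scripts/acceptance.R` (repository root) runs exactly these studies plus
the solver verification benchmarks from a single seed and writes every
headline number to JSON; `inst/scripts/laawash-cli.R` exposes the same
runs as shell subcommands.
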