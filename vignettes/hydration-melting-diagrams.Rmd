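---
title: "Protein hydration melting diagrams: model, estimation and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Protein hydration melting diagrams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydromelt)
```

## The physical picture

A frozen protein solution warmed slowly through equilibrium states releases
its water molecules into rotational motion one binding environment at a
time. Wide-line ¹H NMR separates mobile from immobile protons: immobile
proton pairs produce a fast, solid-like (Gaussian) decay of the
free-induction decay (FID), while rotating water protons produce a slow,
near-exponential component. The slow amplitude extrapolated to `t = 0` is
proportional to the nuclear magnetization `M0 ~ n·B0/T`, so after a
Curie-law `1/T` correction it counts mobile water protons. Normalized by a
total-proton reference it becomes the mobile-water fraction `n`, and `n`
versus temperature is the melting diagram (MD).

Two measurement realities shape the pipeline:

* the first 6–8 µs after the pulse are lost in the receiver dead time, so
  the `t = 0` amplitude must come from a fitted model, never from
  polynomial extension of the visible points;
* points between −1 and 0 °C are dominated by the bulk ice transition and
  are flagged unreliable and excluded from fitting.

## Scales and the energy calibration

Temperature is carried as the normalized fundamental temperature
`T_fn = T/273.15`, i.e. thermal energy `k_B·T` normalized to the melting
point of ice. The Waugh–Fedin relation `E0 = c·R·T` converts the
temperature at which a motion sets in into the potential barrier that was
inhibiting it. The proportionality constant is calibrated on the melting of
bulk ice:

```{r}
cal <- calibrate_c(6.01, 273.15)   # latent heat of ice over R*T at 0 degC
cal
```

`c = 2.65` corresponds to ≈ 5.3 thermally active degrees of freedom per
water molecule — the right range for a rotating (not translating) electric
dipole. All downstream arithmetic uses the full-precision value; 2.65 is a
display convention. The gas constant defaults to 8.317 J/mol·K so worked
examples match the published tables; it is a plain argument of
`physical_constants()` and can be set to the CODATA value. One published
inconsistency is worth noting: the source tables place the plateau start of
both example proteins at "−43 °C" while their `T_fn` values (0.832, 0.835)
correspond to −45.9 and −45.1 °C; this package follows the `T_fn` values
and computes Celsius from them.

## The melting-diagram model

```
n(T_fn) = 0                                         below the onset
          rising step                               onset ... T_fno
          A                                         T_fno ... T_fne   (plateau)
          A + B(T_fn−T_fn1) + C(T_fn−T_fn2)^2 + ... above T_fne
```

The onset step is sharp (≈ 0.01 kJ/mol wide on the energy scale, i.e.
~0.002 `T_fn` units — in practice narrower than one measurement grid bin).
The plateau is the homogeneously bound first hydration shell: no new water
mobilizes there. Above `T_fne` protein–water bond energies spread up toward
water–water bond energies; this heterogeneous region is what distinguishes
intrinsically disordered from globular proteins.

The differential melting diagram (DMD), `Δn/ΔT_fn`, is the distribution of
potential-energy barriers. `dmd_analytic()` renders the onset as a finite
bar of area `A` over the onset bin and the rise as `B + 2C(T_fn−T_fn2)`;
`dmd_numeric()` provides the model-free centered-difference oracle. The two
are tied together by exact integral identities (`integrate_dmd()` over
`[onset, 1]` equals `n(1)`), which the test suite verifies both in closed
form and by grid-refinement convergence.

### Identifiability and anchors

The anchors `T_fn1`, `T_fn2` are not identifiable jointly with `A` (a
linear term's intercept folds into the plateau level). The fit therefore
estimates the re-parameterized rise `A + B'(t−T_fne) + C'(t−T_fne)²` with
continuity `n(T_fne) = A` built in, and reports `T_fn1 = T_fn2 = T_fne` by
convention. Continuity at the plateau end is the only constraint the
plateau logic implies.

## Estimation choices

**Onset.** The onset is the first sustained crossing of `n` above a
threshold, located by linear interpolation between the bracketing points.
The default threshold is `max(3·σ̂, 0.01·max(n))`, where `σ̂` is a robust
noise estimate from successive differences; the 1 % floor guards against a
noise estimate deflated by the clamped frozen baseline, and the
"sustained" requirement (the next point must also exceed the threshold)
makes isolated baseline spikes harmless. When the step is unresolved by the
grid the threshold crossing degenerates to the lower bracketing point, so
the interpolation level is raised to the midpoint of the bracketing
amplitudes — identical for resolved onsets, unbiased for sharp steps.

**Plateau.** An initial plateau is the longest contiguous run of points
whose finite-difference slope stays within `slope_tol` (default 3× the
propagated noise slope) over at least `min_span = 0.02` in `T_fn`. The
plateau end is then refined on a continuous scale by segmented least
squares: plateau mean plus a polynomial rise continuous at the breakpoint.
Two rise families are tried — *tangential* (curvature only; the derivative
is continuous at `T_fne`) and *kinked* (slope + curvature) — and the kinked
one is accepted only if it improves the BIC by 2. The reason is
statistical: when the rise leaves the plateau tangentially, the breakpoint
and the kink slope are nearly unidentifiable together, and the
unconstrained breakpoint wanders (median error ≈ 0.017 on the
ubiquitin-like archetype versus ≈ 0.009 with the selection rule), while
data with a genuine kink select the kinked family decisively. If no run
qualifies, `t_fno = t_fne = onset` is returned — the no-plateau IDP limit
is a result, not an error.

The reported `t_fne` uncertainty is the half-width of the RSS profile
interval within one per-point noise variance of the minimum (at least half
a grid bin). On 35-point grids this is typically 0.004–0.03; order
parameters that divide by `(1 − T_fne)` inherit roughly six times this
error, which is why single measurements carry visibly wider HeR bands than
seed medians.

**Plateau level.** `A` is the unweighted mean of the plateau points (an
error-weighted option exists, but published tables give no per-point
weights, so unweighted is the default). Its standard error is the plateau
scatter over `sqrt(m)`.

**Rise.** Least squares with continuity enforced, starting quadratic; a
cubic term is admitted only on a BIC improvement of 6. A negative fitted
initial slope is unphysical for a melting diagram (it must be
nondecreasing) and triggers a curvature-only refit. An under-determined
rise falls back to linear with a warning.

**Counts.** A fraction of total water converts to waters per protein
molecule via the mole ratio `water_molarity / (concentration /
molecular_weight)`. Water molarity defaults to 55.35 mol/L (pure water near
0 °C); published per-molecule counts are consistent with this convention.
`n_he` is taken from the highest reliable point (`T_fn ≥ 0.97` by default)
minus `n_ho` and is always flagged a lower bound — the region near
`T_fn = 1` is unreliable, so part of the heterogeneous water may be missed.
The same quantity is recomputed as the DMD area over `[T_fne, ≈1]`; the
agreement of the two routes is the method's built-in self-check and a
standing test.

**Limits.** `T_fn = 1` is the ceiling of the melting scale — all water is
mobile at the ice melting point — so plateau boundaries measured above 0 °C
(bulk water) are clamped to 1 before computing order parameters, giving the
homogeneous limits HeR = 0 and HeM = 0 (flagged).

## The synthetic generator

`generate_md()` draws the piecewise model on a grid of 35 temperatures from
−70 to −1 °C (the reliable measurement window) and adds homoscedastic
Gaussian noise, default sd 0.002 — the point scatter of a well-averaged
wide-line measurement. `generate_fid_series()` goes one layer deeper: at
each temperature the slow FID amplitude is `n·T_ref/T` (Curie law), the
fast amplitude is constant (protein protons), and traces are sampled after
the dead time with additive noise. Three presets encode the archetypes:
`ubiquitin_like` (globular: plateau 0.832–0.961, A = 0.019, quadratic rise
to 0.028 at `T_fn` 0.995), `erd10_like` (disordered: plateau 0.835–0.889,
A = 0.0157, rise to 0.1137) and `bulk_water_like` (a single step at
`T_fn = 1`, sampled past 0 °C so the all-mobile region registers as a
plateau). The onset step is rendered as a linear ramp of width 0.0004
`T_fn` ending at `T_fno`.

What the generator emulates: two-component decays, dead-time truncation,
Curie scaling, onset/plateau/rise geometry, homoscedastic point noise.
What it does not: spectrometer artifacts (ringing, phase errors, field
drift), temperature-dependent relaxation times, hysteresis between cooling
and warming branches, or heteroscedastic noise near the bulk transition.
Passing recovery tests therefore validate the estimation pipeline under the
stated statistical model, not instrument-specific systematics.

All randomness enters through explicit integer seeds; identical seeds give
bit-identical outputs, and no global RNG state leaks.

## Recovery performance and known limitations

At noise sd 0.002 on the default grid (100 seeds, median absolute errors):
the ubiquitin-like archetype recovers `A` to ≈ 1.7 %, `T_fno` to ≈ 0.001
and `T_fne` to ≈ 0.009; the ERD10-like archetype recovers `T_fno` to
≈ 0.005 and `T_fne` to ≈ 0.002, but `A` only to ≈ 2.9 %. The latter is a
hard information limit, not an estimator defect: that plateau spans seven
grid points, so even with the true boundaries known the plateau mean has a
median error of 3.2 % at this noise level, and the efficient joint estimate
using the continuity constraint still measures 2.8 %. Tighter recovery of
`A` for narrow-plateau (IDP-like) proteins requires denser sampling or
lower noise, not different software. Noiseless data are recovered exactly
(to optimizer precision, ≈ 1e−6 on the rise coefficients).

Problem sizes throughout the tests — 35-point diagrams, 100-seed recovery
studies, FID traces of a few hundred samples — are the package's chosen
defaults and complete in seconds.

Out of scope by design: frequency-domain (spectrum-width) analysis, T1/T2
relaxometry and echo protocols, DSC modelling of the plateau region,
cooling-branch hysteresis, and H-bond counting from amino-acid composition.
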