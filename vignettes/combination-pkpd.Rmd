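---
title: "Coupled PK/PD simulation of anticancer drug + itraconazole combinations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupled PK/PD simulation of anticancer drug + itraconazole combinations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(combopkpd)
```

## The model

`combopkpd` simulates how the cytotoxic effect of an anticancer drug (ACD;
gemcitabine or 5-fluorouracil) evolves in a patient over time, and how a
co-administered repurposed drug (itraconazole) changes that effect. It
couples two standard components:

**Disposition.** Each drug follows a linear two-compartment intravenous
model in amounts (mg): a central (plasma) compartment of volume $V_{d1}$
(mL), a peripheral (tissue) compartment of volume $V_{d2}$, first-order
exchange $k_{12}$, $k_{21}$ (min$^{-1}$) and clearance $CL$ (mL min$^{-1}$)
from plasma:

$$\frac{dA_1}{dt} = r(t) - k_{12}A_1 + k_{21}A_2 - \frac{CL}{V_{d1}}A_1,
\qquad \frac{dA_2}{dt} = k_{12}A_1 - k_{21}A_2,$$

with $r(t)$ the infusion rate (an IV bolus is an instantaneous jump of
$A_1$). Concentrations are reported in µg mL$^{-1}$
($A/V \times 1000$). Derived constants are $k_{10} = CL/V_{d1}$,
$V_{ss} = V_{d1} + V_{d2}$ and the hybrid rate constants
$\lambda_{1,2}$, the roots of
$\lambda^2 - (k_{10}+k_{12}+k_{21})\lambda + k_{10}k_{21} = 0$
($\lambda_1$ is the larger root by convention).

**Effect.** The percent cell-growth inhibition measured in MTT assays is
described by a four-parameter Hill curve evaluated at the *tissue*
concentration $c_T(t)$:

$$E(t) = \mathrm{Bottom} + \frac{\mathrm{Top} - \mathrm{Bottom}}
{1 + \left( c_T(t) / EC_{50} \right)^{-s}}.$$

In combination runs only the curve floor responds to itraconazole; its
dependence on the itraconazole tissue concentration $x$ (µg mL$^{-1}$) is
quadratic, $\mathrm{Bottom}(x) = a x^2 + b x + c$, recalculated at every
time step. Top, steepness and $EC_{50}$ are fixed at the averages of the
fitted combination curves. Scenarios are scored by
$\mathrm{AUC}_{\mathrm{effect}}$, the area under the effect-time curve —
a scalar that rewards both a high plateau and a long-lasting effect.

Two modeling assumptions are inherited from the underlying experimental
system and should be kept in mind: the tumor is assumed to behave like the
pooled tissue compartment, and the two drugs are assumed not to interact
pharmacokinetically (no shared transporters or metabolic routes), so the
coupling is purely pharmacodynamic.

## Parameters that matter

| Parameter | Units | Default | Why |
|---|---|---|---|
| `h` | min | 0.02 | Step of the fixed-step integrator; small enough that RK4 agrees with the closed form to < 1e-6 relative. |
| `method` | — | `"rk4"` | Fourth-order Runge-Kutta; `"euler"` available for comparison (~1e-3 accurate at the same step). |
| `t_end` | min | 400 (gemcitabine), 200 (5-FU) | Long enough for the effect to reach its floor. AUC-validation runs extend to 25 terminal half-lives so the plasma curve is effectively eliminated. |
| itraconazole MW | g mol$^{-1}$ | 705.64 | Converts the µM-labelled dose-response panels to the µg mL$^{-1}$ scale the disposition model uses. |
| itraconazole doses | mg | 100 / 300 / 500 | 60-min infusions; rates stored exactly as dose/duration (rounded 1.7/5/8.3 mg min$^{-1}$ variants available). |
| AUC window | min | full grid | $\mathrm{AUC}_{\mathrm{effect}}$ ratios are strongly window-sensitive, so the window is always explicit and logged. |

The bundled reference parameter sets (three drugs, eight Hill curves, two
bottom quadratics, the dosing regimens) live in `inst/extdata/` and load
through `drug_fixtures()`.

## Numerical choices

* **Per-step constant input.** The infusion rate is resolved once per step
  (left-endpoint lookup, events snapped to the grid). Each step therefore
  integrates an exactly linear constant-input system, so RK4 keeps its full
  order across infusion start/stop discontinuities. The integrator core is
  compiled (Rcpp): elimination-horizon runs for itraconazole take ~700k
  steps and complete in well under a second.
* **Bolus as a state jump.** A bolus is added to the plasma amount at its
  grid node before the node is recorded; $C_{max}$ of a bolus is the
  concentration at $t = 0^+$, and mass balance
  (plasma + tissue + eliminated = administered) holds at every recorded
  index to < 1e-6 relative.
* **Running AUC.** The accumulator uses left-rectangle increments
  ($\mathrm{AUC}_t = \mathrm{AUC}_{t-dt} + \mathrm{value}_{t-dt}\,dt$),
  mirroring the bookkeeping-compartment formulation of the simulation
  models this package follows; a trapezoidal variant exists for comparison
  with literature AUCs. For curves that start and end at zero the rectangle
  error is $O(h^2)$ and invisible at $h = 0.02$; for a bolus the $t=0$
  jump contributes about $+h\,C_0/2$ (≈ +0.09% for the 5-FU reference run),
  still well inside the 0.5% validation band against $\mathrm{Dose}/CL$.
* **Degenerate cases.** The closed-form oracle switches to the
  $t e^{-\lambda t}$ limit when the two hybrid rate constants coincide;
  the Hill function returns Bottom at zero concentration (the analytic
  limit of the singular negative power); effects are *not* clamped to
  [0, 100] — fitted floors can be negative and clamping would bias
  $\mathrm{AUC}_{\mathrm{effect}}$ — instead negative-effect intervals are
  flagged.

## Identifiability and estimation

`fit_two_compartment()` fits the closed-form solution to plasma
concentration-time samples by Levenberg-Marquardt on log-scale parameters
(which enforces positivity). The tissue volume $V_{d2}$ never enters the
plasma kinetics of the amount-based model — it only rescales the tissue
concentration — so it is structurally unidentifiable from plasma data. The
fitter therefore estimates the four identifiable constants
($V_{d1}, CL, k_{12}, k_{21}$) and reports the partition-consistent value
$V_{d2} = V_{d1} k_{12}/k_{21}$, which is the convention the bundled
reference sets themselves obey to printed rounding. The objective is
unweighted least squares by default (an optional $1/\hat y^2$ weighting is
exposed); per-parameter CV% comes from the asymptotic covariance at the
optimum, with a pseudo-inverse guarding the near-singular information
matrices that weakly identified transfer constants produce. A small
multi-start with two polish restarts makes the fit robust to factor-of-two
initialization errors even on the worst-conditioned reference set.

`fit_hill()` fits the four Hill parameters with steepness and $EC_{50}$ on
the log scale; `fit_bottom_quadratic()` interpolates the floor quadratic
exactly through three calibration points (the 2 µM co-incubation floor is
excluded from calibration, consistent with the averaging rules below) and
falls back to least squares for more points. Exact three-point
interpolation through the 0/4/6 µM floors reproduces the reference
quadratic coefficients to two decimals, which is why interpolation is the
default calibration path.

**Averaging rules.** The shared combination curve uses arithmetic means of
Top, steepness and $EC_{50}$ across the four co-incubation levels, with
two exclusions taken from the reference tables' own footnotes: the 2 µM
floor (an outlier below even the control floor) and the control curve's
steepness (a degenerate fit with an astronomically large CV). Honoring the
steepness exclusion moves the gemcitabine average from 9.29 to 4.67.

## What the synthetic generator emulates — and what it does not

`generate_cp_profile()` draws sparse concentration-time samples from the
closed-form model with multiplicative lognormal noise (sd 0.05 by default:
PK assays tend to have constant CV), emulating literature-style sampling
(14 points over 0–210 min for the ACD designs). `generate_dose_response()`
draws MTT-style replicate panels around a Hill curve with additive
Gaussian noise (sd 3 percentage points, 3 replicates × 8 log-spaced
concentrations). Both are byte-deterministic under a fixed seed.

The generator reproduces the *statistical shape* of such data only: it
does not model assay optics, plate effects, between-subject variability,
or model misspecification. Passing recovery tests therefore demonstrate
the correctness and conditioning of the estimation machinery, not that
real clinical or assay data of this quality would yield equally tight
estimates.

## Effect collapse and its onset

While the ACD tissue concentration is far above $EC_{50}$, the Hill power
$f(c) = (c/EC_{50})^{-s}$ is negligible and the effect sits on a plateau
near Top (≈ 73% for the gemcitabine combination, ≈ 59% for 5-FU). Once the
concentration decays toward $EC_{50}$, $f$ grows exponentially and the
effect collapses to the itraconazole-controlled floor;
`collapse_diagnostic()` exposes $f$ itself.

Two onset definitions are provided, and they genuinely differ:

* `drop_onset_time()` — first post-peak time the *tissue concentration*
  crosses a stated threshold;
* `effect_drop_onset()` — first post-peak time the *effect* leaves its
  plateau by a stated fraction (default 1%) of the dynamic range.

For the 5-FU reference run these land ~24 min apart (≈ 92 min for the
0.5 µg mL$^{-1}$ concentration crossing vs ≈ 68 min for plateau
departure), because with a steepness near 2.4 the effect visibly bends
well before the concentration reaches any given threshold. The
plateau-departure diagnostic is the one that matches a visual reading of
effect-time curves; the concentration-threshold operation is kept because
its contract is simpler and grid-independent.

## Multiple dosing

Three routes extend a combination scenario to repeated itraconazole
administrations, and they cross-validate each other:

* `ode_repeat` — the integrator handles repeated regimens natively;
* `superposition` — sums time-shifted closed-form single-dose solutions
  (valid by linearity; agrees with the direct route to ~1e-14);
* `css_approximation` — pins the plasma concentration at a steady-state
  value $C_{ss}$ and lets the tissue amount relax analytically to
  $A_2^{ss} = k_{12} C_{ss} V_{d1} / (1000\,k_{21})$, i.e. a tissue
  concentration of $(k_{12} V_{d1})/(k_{21} V_{d2}) \times C_{ss}$. This
  mode mirrors the spreadsheet workaround sometimes used when a simulation
  tool cannot repeat infusions, and is useful for "what if exposure were
  sustained" questions.

## Problem sizes used by the test suite

The shipped tests run the reference grids (h = 0.02 min; 400/200 min
horizons; elimination-horizon AUC runs to 25 terminal half-lives, ~700k
steps for itraconazole), a 3000-min three-dose superposition check, 10
random-restart fits per drug, and the two noisy-recovery studies (seeds 1
and 7). The full suite completes in a few seconds thanks to the compiled
integrator core.

## Known limitations

* The disposition model is a two-compartment mammillary structure: no
  physiological organs, no oral absorption, no protein-binding correction,
  no saturable elimination.
* The pharmacodynamic coupling is empirical (a calibrated quadratic on the
  curve floor), valid only over the calibrated itraconazole range
  (0–4.23 µg mL$^{-1}$ tissue concentration); evaluations beyond it are
  flagged, and the 300/500 mg dose scenarios do extrapolate.
* Relative $\mathrm{AUC}_{\mathrm{effect}}$ gains between scenarios depend
  strongly on the integration window; the package reports them with the
  window attached rather than treating any particular percentage as a
  model constant.
* No synergy index (Bliss, Loewe, ...) is computed;
  $\mathrm{AUC}_{\mathrm{effect}}$ is the only combination score.
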