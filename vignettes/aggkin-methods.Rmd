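---
title: "Methods: aggregation kinetics, mechanism selection and synthetic data in aggkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: aggregation kinetics, mechanism selection and synthetic data in aggkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aggkin)
```

## The kinetic model and its assumptions

`aggkin` analyses unseeded amyloid fibrillization with the standard
nucleation–elongation moment equations: fibril number concentration $P$ and
fibril mass concentration $M$ (monomer equivalents) evolve as

$$\frac{dP}{dt} = k_n m^{n_c} + k_2 m^{n_2} M, \qquad
  \frac{dM}{dt} = 2 k_+ m P, \qquad m = m_0 - M,$$

starting from isolated monomer ($P(0)=M(0)=0$). The three microscopic rate
constants are primary nucleation $k_n$, secondary (fibril-surface-catalysed)
nucleation $k_2$, and elongation $k_+$; $n_c$ and $n_2$ are the reaction
orders of the two nucleation steps. Substituting $u = M/m_0$ and
$q = 2k_+P$ shows that the *normalized* kinetics depend on the microscopic
rates only through the two effective rates

$$\lambda = \sqrt{2 k_+ k_n m_0^{n_c}}, \qquad
  \kappa = \sqrt{2 k_+ k_2 m_0^{n_2+1}},$$

i.e. through the combined constants $\sqrt{k_n k_+}$ and $\sqrt{k_+ k_2}$.
This is why `fit_global()` reports only the combined constants: individual
rates are structurally unidentifiable from unseeded data, and are exposed
only inside constrained mechanism fits where a baseline pins the others.

Assumptions inherited from the model: no seeds, no fragmentation, no
off-pathway oligomers, mass conservation $m + M = m_0$. Seeded kinetics
($M(0)>0$) are deliberately unsupported.

### Reaction orders

The defaults are $n_c = 2$, $n_2 = 2$, the standard choice for Aβ42 in the
global-fitting literature; both are arguments everywhere. Fits of the
half-time scaling exponent $\gamma$ (below) are the practical diagnostic:
secondary-dominated kinetics give $\gamma \approx -(n_2+1)/2 = -1.5$,
purely primary kinetics $\gamma \approx -n_c/2$.

### Units

All computation is in molar and seconds, matching the units in which
combined constants are conventionally reported
($\mathrm{M^{-1}s^{-1}}$ and $\mathrm{M^{-3/2}s^{-1}}$ for $n_2=2$).
Ingestion converts the metadata's micromolar columns; `hours_to_seconds()`
is provided for time axes.

## The closed form and its oracle-corrected coefficients

The closed-form solution evaluated by `fibril_mass_fraction()` is the
first-order self-consistent solution of the moment equations,

$$\frac{M(t)}{M(\infty)} = 1 -
  \left( \frac{B_+ + C_+}{B_+ + C_+ e^{\kappa t}} \cdot
         \frac{B_- + C_+ e^{\kappa t}}{B_- + C_+} \right)^{k_\infty^2 / (\kappa \tilde k_\infty)}
  e^{-k_\infty t}.$$

The textbook coefficient forms are
$C_\pm = \pm\lambda^2/(2\kappa^2)$,
$k_\infty = \sqrt{2\kappa^2/(n_2(n_2+1)) + 2\lambda^2/n_c}$,
$\tilde k_\infty = \sqrt{k_\infty^2 - 4C_+C_-\kappa^2}$,
$B_\pm = (k_\infty \pm \tilde k_\infty)/(2\kappa)$. Validated against the
package's independent moment-ODE integrator these analytic forms deviate by
up to $\sim 5\times10^{-3}$ (max absolute mass-fraction error over five
half-times) — the intrinsic accuracy of the first-order solution, constant
across the secondary-dominated regime. Because the package treats the ODE
integrator as authoritative, the coefficients are *corrected numerically
against it*:

1. a 3-parameter refinement of $(k_\infty, \tilde k_\infty, C_+)$ with the
   $B_\pm$ ties kept, which is smooth in $r = \lambda/\kappa$ and is frozen
   into a calibration table over $\log_{10} r \in [-4.2, -0.8]$
   (regenerated nodes are checked by a unit test);
2. for $r > 0.05$, where the table's residual error approaches the
   tolerance, a per-ratio refinement that frees all five printed constants
   ($B_+, B_-, C_+, k_\infty, \tilde k_\infty$), accepted only when it
   lowers the max error, cached per ratio so repeated conditions (e.g. the
   same dose across seeds) reuse it.

The corrected closed form matches the ODE to $\le 7\times10^{-4}$ across
$\kappa/\lambda \in [10, 10^4]$. `fibril_mass_fraction()` and the
synthetic-data generator share this exact path. Fit objective evaluations
use the frozen table throughout (per-call calibration is unaffordable
inside optimizer loops); the two paths coincide for $r \le 0.05$, which
covers the whole secondary-dominated design, so generate → fit round trips
there are exactly self-consistent, and for $r \in (0.05, 0.1]$ the residual
table error ($\sim10^{-3}$) is far below the measurement noise fits see.
Fits fall back to the ODE integrator when $\kappa/\lambda \le 10$, where
the closed form's derivation (secondary dominance) breaks down; with
$\kappa = 0$ the closed form is singular and a degenerate-model error
directs callers to the ODE path. With $k_n = 0$ the unseeded reaction never
starts; the analytic skeleton does not reproduce this limit, so it is
special-cased to return zero.

The ODE integrator itself is a fixed-substep classical RK4 on the reduced
$(u, q)$ system (the system is smooth and non-stiff; step size is bounded
by 0.01 in units of $1/\max(\lambda,\kappa)$, giving self-convergence at
the $10^{-9}$ level). An external ODE library was not available in the
target environment; the 2-state integrator is small enough to own and is
cross-validated against the closed form and against analytic scaling laws.

## Trace processing

* **Baseline/plateau windows**: 5 initial and 10 final points by default
  (the assay protocol does not prescribe windows; these are configurable).
  The baseline mean uses only *pre-transition* points — points before the
  signal first exceeds 10 % of its amplitude. On a shared plate grid the
  fastest wells can enter their transition within the first few cycles (at
  the default synthetic design the 9 µM well has roughly 7 grid points per
  half time), and a blind first-window mean would eat into the lag phase
  and distort the normalized curve by tens of percent.
* **Normalization order**: each replicate is normalized before averaging,
  which is robust to gain differences between wells.
* **Endpoint vs fitted plateau**: `plateau = "endpoint"` (default) uses the
  endpoint window mean; `plateau = "fitted"` takes both anchors ($F_0$ and
  $F_0+A$) from the sigmoidal fit, which is preferable when traces are
  truncated before a clean plateau but measurably *biased* for the
  asymmetric slow-tailed curves of mixed primary/secondary regimes (the
  symmetric logistic underestimates their plateau). Since generated and
  typical experimental grids span four half-times of the slowest well,
  endpoint is the default everywhere.
* **Non-aggregating wells** (plateau/baseline < 1.2-fold) are flagged and
  excluded from kinetic fits but kept, baseline-corrected, for endpoint
  analyses — high-dose wells in an inhibition series may never plateau.
* **Shared time grids** are required within a plate (plate readers emit
  common cycles); no resampling is attempted.

## Fitting

All nonlinear fits run on log-transformed positive parameters, with a
10-point Latin-hypercube multi-start (fixed seed 1730) screened coarsely
and the best three starts polished by Nelder–Mead with a restart. Fits are
therefore deterministic given the data and seed; the optimizer never
consumes the global RNG stream.

* **Sigmoidal fits** use Gauss–Newton (`nls`, port algorithm) from a
  deterministic data-driven start ($F_0$/$A$ from the windows, $\tau_{1/2}$
  from the first half-amplitude crossing, $r_\mathrm{max}$ from
  $4\cdot\max$ slope$/A$), with a deterministic multi-start and a
  Nelder–Mead pre-optimization as fallbacks; the `converged` flag is
  honest.
* **Global fits** share the two combined constants across all
  concentrations and curves; asymptotic standard errors come from the
  numerical Jacobian at the optimum. The search box is
  $\log_{10}\sqrt{k_nk_+} \in [-2, 3]$,
  $\log_{10}\sqrt{k_+k_2} \in [2, 8]$.
* **Mechanism fits**: with the zero-dose baseline $(\lambda_0, \kappa_0)$
  fixed (fitted from the zero-dose curves or supplied), each hypothesis
  scales one microscopic rate by a per-dose factor $f_d$:
  $k_n$ free scales $\lambda$ by $\sqrt{f_d}$; $k_2$ free scales $\kappa$
  by $\sqrt{f_d}$; $k_+$ free scales both (it enters both pathways). Each
  $f_d$ is a 1-D bounded optimization, so the fit is separable and fast.
* **χ² convention**: the assay literature prints χ² values without defining
  them, so the package documents its own: residual sum of squares divided
  by $\hat\sigma^2 (N - p)$. For a single fit $\hat\sigma$ is estimated
  from pre-transition residuals. For mechanism *ranking* a common
  $\hat\sigma$ is used for all hypotheses, estimated from pooled second
  differences of the observed curves (which cancel the smooth trend):
  per-hypothesis noise estimates turn out not to be ranking-safe, because a
  poorly fitting hypothesis inflates its own $\hat\sigma$ and so deflates
  its χ². Only the ordering of hypotheses is interpreted.
* **Amplitude handling**: fits assume curves normalized to 0–1 and do not
  refit per-curve amplitudes; ingestion defensively renormalizes curves
  that are clearly not on that scale. This resolves an ambiguity in the
  protocol (whether per-curve nuisance amplitudes were refit) in favour of
  the simpler, better-identified choice.

### Half-time scaling

`fit_halftime_scaling()` is ordinary least squares of $\log\tau_{1/2}$ on
$\log m_0$; the slope is the $\gamma$ exponent. For the reference
uninhibited constants over 1.5–9 µM the model-implied $\gamma$ is about
$-1.4$, between the pure-secondary limit $-1.5$ and the weakening effect of
the primary pathway at low concentration.

## Turbidity dose-response

Holdase-type chaperone activity is quantified from endpoint turbidity:
per experiment block, each well's baseline-corrected final intensity
(mean of the last 10 points) is normalized to the block's substrate-alone
mean; within-block replicates are averaged first, then mean ± SD is taken
across blocks — the "mean ± SD of $n$ experiments performed in triplicates"
convention. Normalizing per block cancels multiplicative block gains
exactly, which the block-gain robustness test exploits. No significance
testing is attached (none is standard for this assay); `compare_chaperones()`
only flags ratios whose mean ± SD intervals do not overlap. Hill/IC50
fitting is out of scope.

## The synthetic-data generator

The generator emulates the two standard ThT designs — an
eight-concentration unseeded series (1.5, 2, 2.5, 3, 4, 5, 7, 9 µM, four
replicates) and a fixed 3 µM dose series at molar ratios
0, 0.1, 0.3, 0.5, 0.7, 1 — and a turbidity design (600 nM substrate, 2 h at
60 s cycles, 3 blocks × 3 replicates). Choices that are the package's own,
with rationale:

* **Noise model**: additive i.i.d. Gaussian, SD = 2 % of the amplitude.
  The minimal model under which parameter-recovery statements are
  meaningful; no instrument drift, evaporation or edge effects.
* **Time grid**: spans 4 half-times of the slowest condition with 400
  points by default (≈ 2-minute reader cycles over a typical 12–16 h run).
  Denser-than-minimal sampling matters: the fastest well's transition must
  be resolved by several cycles or normalization and fitting degrade, which
  is equally true of real plate data.
* **Inhibitor action**: multiplicative factors on the targeted rate(s),
  1 at dose 0, interpolated between tabulated doses. The default map
  (1, 0.7, 0.45, 0.3, 0.2, 0.12 over ratios 0–1) mirrors a strong
  secondary-nucleation suppressor; factor values are generator choices,
  not literature values.
* **Turbidity traces**: logistic rise anchored at 0, plateau scaled by a
  residual-fraction map (default: near-complete suppression, fraction 0.05,
  at 1:1), multiplicative uniform block gains (±10 % by default) and
  additive noise.
* **Determinism**: everything derives from the seed; the truth record
  (JSON) stores all parameters, per-condition $\lambda$, $\kappa$ and half
  times, so every expected pipeline output is recomputable.

What a green test on synthetic data does **not** establish: correctness of
the noise model for real instruments, robustness to drift/outliers, or the
physical truth of the nucleation model itself — only that the pipeline
inverts data generated under its own stated assumptions.

## Numerical edge cases

* $\kappa = 0$: closed form errors (degenerate model); ODE path handles it.
* $\lambda = 0$: mass fraction identically zero (special-cased).
* $k_+ = 0$: no elongation; $P$ grows linearly, $M \equiv 0$ (special-cased
  in the integrator).
* Large $\kappa t$: the closed form is evaluated with $e^{-\kappa t}$
  factored so it never overflows.
* Flat traces: flagged before any fit touches them; `fit_sigmoidal`
  refuses flagged wells unless told otherwise.

## Known limitations

* Individual $k_n$, $k_+$, $k_2$ are never reported from unseeded data —
  only combined constants and constrained per-dose factors.
* The closed form is trusted only for $\kappa/\lambda > 10$; mixed regimes
  run on the (slower) ODE path.
* Replicates must share a time grid; no interpolation is offered.
* The χ² scale is package-specific; compare values only within a run.
* Printed χ² values from other software cannot be reproduced without the
  underlying raw traces; only orderings are comparable.
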