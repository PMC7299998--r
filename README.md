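# aggkin

Analysis of protein aggregation kinetics and chaperone activity from
plate-reader assays, written for the workflow in which a molecular chaperone
(e.g. a BRICHOS domain) is tested against amyloid fibril formation of Aβ42
(thioflavin T fluorescence) and against amorphous aggregation of destabilized
model substrates such as citrate synthase or rhodanese (turbidity / light
scattering at 360 nm).

## The model

Unseeded fibril formation is described by the moment equations of the
nucleation–elongation master equation,

    dP/dt = kn·m^nc + k2·m^n2·M        (primary + secondary nucleation)
    dM/dt = 2·k+·m·P                   (elongation),  m = m0 − M

with fibril number P, fibril mass M (monomer equivalents) and free monomer
m. The normalized solution depends on the microscopic rates only through

    λ = √(2·k+·kn·m0^nc)      κ = √(2·k+·k2·m0^(n2+1))

so unseeded data identify only the combined constants √(kn·k+) and
√(k+·k2). The package evaluates the closed-form fibril mass fraction

    M(t)/M(∞) = 1 − [ (B₊+C₊)/(B₊+C₊e^{κt}) · (B₋+C₊e^{κt})/(B₋+C₊) ]^{k∞²/(κk̃∞)} · e^{−k∞t}

with coefficients corrected against a built-in moment-ODE reference
integrator (max deviation ≤ ~7·10⁻⁴ in mass fraction for κ/λ ∈ [10, 10⁴]),
and provides:

* `fit_sigmoidal()` — empirical logistic fits, extracting the half time τ½
  and the growth-rate parameter r_max;
* `fit_global()` — multi-concentration global fits with √(kn·k+) and
  √(k+·k2) shared across all monomer concentrations;
* `fit_constrained_mechanism()` — inhibitor mechanism selection: for a dose
  series, each hypothesis lets only one of kn, k+, k2 respond to the
  inhibitor; hypotheses are ranked by reduced χ²;
* `fit_combined_free()` — per-dose relative combined rate constants;
* `fit_halftime_scaling()` — the γ exponent (slope of log τ½ vs log m0),
  diagnostic of the dominant nucleation pathway;
* `dose_response()` — turbidity endpoint analysis: normalized final
  intensities vs chaperone:substrate molar ratio, mean ± SD across
  experiment blocks;
* `generate_tht_plate()` / `generate_turbidity_plate()` — deterministic
  synthetic plate generators with full ground-truth records, emitting the
  same CSV dialects `load_plate()` reads.

## Worked example

Simulate the standard eight-concentration unseeded design (1.5–9 µM, 4
replicates, 2 % noise) with reference combined constants
√(kn·k+) = 6.4 M⁻¹s⁻¹ and √(k+·k2) = 2.74·10⁵ M^(−3/2)s⁻¹, then refit:

```r
library(aggkin)
rc <- rate_constants_from_combined(6.4, 2.74e5)
plate <- generate_tht_plate(rc, noise_sd = 0.02, n_reps = 4, seed = 11)
norm  <- lapply(load_plate(plate$data, plate$metadata), baseline_and_normalize)
means <- lapply(split(norm, vapply(norm, `[[`, "", "replicate_group")),
                average_replicates)
fit_global(means)
#> <global_fit> 8 curves: sqrt(kn*k+) = 6.25 +/- 0.075 M^-1 s^-1,
#>   sqrt(k+*k2) = 2.76e+05 +/- 8.9e+02, chi2 = 0.948
```

The recovered constants land within a few percent of the generator truth;
the standard errors are asymptotic least-squares errors, and χ² is the
reduced, noise-scaled residual criterion used to compare fits. A mechanism
run on a dose series in which only the secondary-nucleation rate k2 is
suppressed ranks the hypotheses the same way the corresponding fits of
real chaperone data do:

```r
dose <- generate_tht_plate(rc, m0_list = 3e-6, inhib = inhibitor_model("k2"),
                           ratios = c(0, 0.1, 0.3, 0.5, 0.7, 1),
                           noise_sd = 0.02, n_reps = 4, seed = 21)
norm  <- lapply(load_plate(dose$data, dose$metadata), baseline_and_normalize)
means <- lapply(split(norm, vapply(norm, `[[`, "", "replicate_group")),
                average_replicates)
fit_constrained_mechanism(means)
#> <mechanism_selection> reduced chi2 by hypothesis (lower = supported):
#>   k2_free     1.118
#>   kplus_free  2.979
#>   kn_free     31.37
```

## Command line

```sh
inst/cli/aggkin simulate --design dose_series --out sim --seed 1
inst/cli/aggkin fit --plate sim/tht_dose_plate.csv \
    --metadata sim/tht_dose_metadata.csv --out fits
inst/cli/aggkin dose-response --plate sim/turbidity_plate.csv \
    --metadata sim/turbidity_metadata.csv --out dr
```

Every output directory receives the resolved config for provenance.

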