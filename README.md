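# ventsplitr

Desk-scale simulation and analysis of **differential multi-patient
ventilation** through a Y-splitter with 3D-printed orifice flow
restrictors — for respiratory/biomedical engineers who need to size a
restrictor, predict delivered tidal volumes, or quantify how 3D-print
tolerance errors corrupt a restrictor's pressure drop, without a CFD
cluster.

## The model

Each patient branch is a single-compartment RC network driven by a
pressure-control waveform (PEEP baseline, optional exponential rise, hold
at PIP):

```
p_0 = (τ/C) dV/dt + V/C,        τ = R·C + R_bc·(C_bc + C)
```

with compliance `C` (L/cmH2O), airway resistance `R` and breathing-circuit
properties `R_bc`, `C_bc` (defaults 13, 22 cmH2O/(L/s) and 0.004 L/cmH2O).
The restrictor on a port adds a nonlinear series loss, quadratic in the
flow `V̇` (L/min):

```
Δp = a·V̇² + b·V̇
```

with CFD-fitted coefficients for 2/3/4 mm bores and the bare splitter
(`reference_coefficients()`), generalised across diameters by

```
Δp ≈ 3.55·D⁻⁴·⁰³·V̇² + 10.27·D⁻³·⁴⁶·V̇     (D in mm, 2–4 mm, V̇ ≤ 60 L/min)
```

At each time step the simulator solves the monotone scalar balance
`p_vent − Δp(V̇) = (τ/C)V̇ + V/C` by safeguarded Newton iteration inside a
bisection bracket, with implicit-trapezoidal time stepping (1 ms default);
against the closed-form RC step response it is accurate to ~1e-9 L.
Orifice hydraulics (`Re = 4V̇/(πDν)`, the discharge-coefficient pressure
drop, and the fourth-power diameter sensitivity `(D_nom/D_true)⁴`) cover
the print-tolerance arithmetic: a nominally 2.00 mm bore printed at
1.69 mm delivers ~1.96× its design pressure drop.

## Worked example

```r
library(ventsplitr)

# two patients on one ventilator: compliant lung (C = 0.1) behind a 4 mm
# restrictor, stiff lung (C = 0.2) on the bare port
sc  <- default_scenario(restrictor_diameter = 4)
res <- simulate_scenario(sc)
res$summary
#> # A tibble: 2 × 5
#>   branch       diameter_mm peak_pressure_drop_cmH2O peak_flow_Lmin end_inspiratory_volume_L
#>   <chr>              <dbl>                    <dbl>          <dbl>                    <dbl>
#> 1 restricted             4                    10.3            24.5                    0.473
#> 2 unrestricted          NA                     0              42.3                    0.808
```

The restricted branch receives 0.473 L by end-inspiration against the
unrestricted branch's 0.808 L: the 4 mm orifice absorbs up to 10.3 cmH2O
at the 24.5 L/min flow peak. To hit a volume target instead, titrate the
inspiratory time:

```r
required_inspiratory_time(sc, "restricted", target_volume = 0.480)
#> [1] 1.269667   # seconds of inspiratory window for 0.480 L through 4 mm
```

Fit a pressure-flow law from (synthetic or real) bench data and estimate
the true bore of an undersized print:

```r
ms  <- gen_bench_measurements(reference_law(2), noise = bench_noise(seed = 1))
fit <- fit_quadratic_law(ms)
glance(fit)
#> # A tibble: 1 × 4
#>   r.squared r.squared.centered  nobs diameter_mm
#> 1     1.000              1.000   200           2
effective_diameter_from_fit(fit)
#> [1] 1.984843   # mm — hydraulic diameter recovered from the fit alone
```

Analyse a printed bore's wall profile (undersizing, layer-ridge feature
size by Fourier analysis, fourth-power pressure inflation):

```r
prof <- gen_wall_profile(nominal = 2, mean_undersize = 0.31,
                         ridge_amplitude = 0.05, layer_thickness = 0.05,
                         noise_sd = 0.003, seed = 3)
summarize_profile(prof)[, 1:5]
#> # A tibble: 1 × 5
#>   mean_internal_diameter_mm peak_to_peak_variation_mm mean_feature_size_mm id_error_to_layer_ratio pressure_inflation_factor
#> 1                      1.69                    0.0132               0.0505                    6.20                      1.96
```

A thin CLI wraps the same functions (`exec/ventsplit`): subcommands
`simulate`, `titrate`, `fit`, `metafit`, `synth`, `tolerance`,
`reproduce`, with YAML scenario configs (see
`inst/extdata/default_scenario.yaml`).

## Acceptance script

`scripts/acceptance.R` re-runs the package's core computations from
scratch — the cross-diameter power-law meta-fit, the pointwise hydraulic
checks, the splitter simulations over all restrictor bores, the
solver-vs-oracle comparison, seeded fit/diameter recovery, titration, and
the print-tolerance round trip — logging each result:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Scope

The package is the lumped surrogate around CFD-fitted restrictor laws; it
does not reproduce finite-volume flow fields, simulate expiration, or
model multi-breath cyclic steady state. See the methods vignette
(`vignettes/splitter-restrictor-model.Rmd`) for assumptions, numerical
choices and known ambiguities.
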