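---
title: "Differential ventilation through a splitter: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential ventilation through a splitter: model, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ventsplitr)
```

## The problem

When one pressure-control ventilator must serve two patients with unequal
lung compliance, a Y-splitter alone over-ventilates the compliant lung. A
small-bore orifice restrictor placed in series with the compliant patient's
port drops the delivered pressure and rebalances tidal volumes. ventsplitr
is a desk-scale simulator of that arrangement: it couples a parametric
pressure-control waveform to a nonlinear restrictor pressure–flow law and a
lumped resistance–compliance (RC) model of each patient and breathing
circuit, and adds the surrounding analyses — coefficient fitting, tidal
volume titration, and the dimensional-tolerance arithmetic that makes
3D-printed restrictors hazardous without calibration.

## The lumped model

Each branch is a single-compartment RC network. With gauge pressures in
cmH2O, volumes in L and flows in L/s, the stagnation pressure $p_0$ at the
splitter outlet drives the inspired volume $V(t)$ through

$$p_0 = \frac{\tau}{C}\frac{dV}{dt} + \frac{V}{C},
\qquad \tau = RC + R_{bc}(C_{bc} + C),$$

where $C$ is the patient's respiratory compliance, $R$ the inspiratory
airway resistance, and $C_{bc}$, $R_{bc}$ the breathing-circuit compliance
and resistance. Defaults are the literature-typical values $R = 13$,
$R_{bc} = 22$ cmH2O/(L/s), $C_{bc} = 0.004$ L/cmH2O. Stagnation and static
pressure are related by Bernoulli's $p_0 = p + \tfrac12 \rho U^2$; at the
22 mm ports the dynamic term is ~0.01 cmH2O and is ignored in the lumped
balance, while `stagnation_to_static()` quantifies it where it matters
(inside a 2 mm throat it reaches ~8 cmH2O).

Volume is measured above the end-expiratory equilibrium at PEEP: the solver
drives the equation with $p_{vent}(t) - \mathrm{PEEP}$ from $V(0) = 0$,
which is equivalent to absolute bookkeeping because the equation is linear,
and makes the end-inspiratory (tidal) volume a direct state readout. Only
inspiration is simulated; expiratory dynamics, intrinsic PEEP and
spontaneous effort are out of scope.

## Restrictor laws

The combined splitter-plus-restrictor pressure loss on a port is a
quadratic in the volumetric flow $\dot V$ (L/min):

$$\Delta p = a\dot V^2 + b\dot V,$$

with per-diameter coefficients for the reference geometry in
`reference_coefficients()` (bores 2, 3, 4 mm and the bare splitter, whose
secant resistance converts to 0.22 cmH2O/(L/s)). We implement the signed
extension $a\dot V|\dot V| + b\dot V$, odd in flow, so the law can only
dissipate: flow reversal is outside the intended regime, but an integrator
must not be able to extract energy from it. Across diameters the
coefficients follow power laws,

$$\Delta p \approx 3.55\,D^{-4.03}\dot V^2 + 10.27\,D^{-3.46}\dot V,$$

which `fit_power_laws()` reproduces from the coefficient table by ordinary
least squares of $\log a$ (and $\log b$) on $\log D$. The fitting method is
not documented for the reference model; log–log OLS recovers all four
published parameters to better than 0.2%, which is strong evidence it is
the generating method, and it is what we use.

The meta-fit is not uniformly tight. Its residual on $b$ is +5.6%, −12.3%
and +7.9% at $D$ = 2, 3, 4 mm, so in the linear-dominated limit
$\dot V \to 0$ the power-law surface deviates from the per-diameter law by
up to ~12%. Once the quadratic term matters (above roughly 3 L/min) the
combined deviation stays within 7%. Tests assert the 7% band on
$\dot V \in [3, 60]$ L/min only.

The ideal-orifice law
$\Delta p = 8\rho\dot V^2 / (\pi^2 c_D^2 D^4)$
is also provided; a widely circulated form of this relation omits the
square on $\dot V$, which dimensional analysis rules out, so the squared
form is implemented. Its $D^{-4}$ dependence is the engine of the
print-tolerance analysis: at fixed flow an undersized bore multiplies the
pressure drop by $(D_{nom}/D_{true})^4$ — a part printed at 1.69 mm on a
2.00 mm design delivers ~1.96× the design drop, and halving the bore gives
exactly 16×.

A note on units: the gas table used for the reference simulations prints
the viscosity $2.02\times10^{-5}$ with dynamic units (Pa·s), but the
Reynolds relation $\mathrm{Re} = 4\dot V/(\pi D \nu)$ uses it as kinematic
(m²/s); only the kinematic reading places the bench operating points in
the stated 5000–8000 turbulent band, so we treat it as kinematic and expose
it as a config value. All user-facing quantities stay in clinical units
(cmH2O, L/min, mm); SI conversion happens only inside hydraulic formulas,
with 1 cmH2O = 98.0665 Pa.

## The driving waveform

The reference simulations were driven by an empirical recording from a
pressure-control ventilator that is not tabulated anywhere, so ventsplitr
uses a parametric stand-in: baseline PEEP, an optional exponential approach
to PIP with time constant `rise_time/3` (95% of the span at `rise_time`),
then a hold at PIP for `pressure_max_time`. The default is `rise_time = 0`
— a pure step — because the step makes the unrestricted branch exactly
solvable, $V(t) = C\,\Delta P\,(1 - e^{-t/\tau})$, giving the integrator an
analytic oracle.

One consequence: a sampled zero-rise waveform contains no PEEP sample (the
step has already happened at $t = 0^+$), so its minimum equals PIP; only
waveforms with a positive rise time start at PEEP. We chose this over
storing a PEEP point at $t = 0$ because linear interpolation across that
jump would withhold part of the driving pressure for one time step and
break the $10^{-6}$ L oracle agreement. The hold time is read as
time-at-maximum; the inspiratory window is `rise_time + pressure_max_time`
and both knobs are exposed rather than guessing the ventilator vendor's
convention.

## Numerics

At each time step the branch balance
$p_{vent} - \Delta p(\dot V) = (\tau/C)\dot V + V/C$
is a scalar equation for the flow, strictly monotone because $a, b \ge 0$
and $\tau/C > 0$. We solve it with safeguarded Newton iteration inside a
maintained bisection bracket (Newton steps that leave the bracket fall back
to bisection), to a flow tolerance of $10^{-9}$ L/s; a stiff DAE solver
would be disproportionate for a guaranteed scalar root. Time stepping is
implicit-trapezoidal with a 1 ms default step: the stored volume series is
exactly the trapezoidal integral of the stored flow series, and the flow at
every node exactly satisfies the balance. Against the closed-form step
response the integrator is accurate to ~$10^{-9}$ L over a 1.25 s window;
halving the step changes the end volume by far less than 0.1%.

The Y-splitter body's own loss is ~0.1 cmH2O, negligible against the
restrictor drops, so the branches are decoupled by default and each sees
the full ventilator pressure. An optional `common_law` couples them through
a shared upstream drop on the total flow (outer monotone solve on total
flow, inner per-branch solves); it defaults off.

## Titration

`titration_curve()` sweeps the inspiratory window up to 5 s and records the
end-inspiratory volume; `required_inspiratory_time()` inverts the monotone
relation by bisection to 1 ms, reporting the smallest window that reaches
the target (default 0.480 L). The asymptotic deliverable volume is
$C(\mathrm{PIP} - \mathrm{PEEP})$ regardless of the restrictor — the
restrictor changes how fast the plateau is approached, not the plateau —
so unreachable targets fail fast with that asymptote in the error. Curve
shapes are asserted only qualitatively (monotone in time; smaller bores
deliver less at fixed time): published titration figures derive from the
full CFD with the empirical inlet waveform and are not numeric targets.

## Fitting conventions

`fit_quadratic_law()` regresses $\Delta p$ on $(\dot V^2, \dot V)$ with no
intercept: the law passes through the origin by physics, and a free
intercept would absorb transducer offset that the synthetic data do not
model. $R^2$ is reported in the zero-intercept convention
($1 - \mathrm{RSS}/\sum y^2$), with the mean-centred value alongside, since
the convention behind the published fit qualities is unstated. OLS is
unweighted: the instrument noise is near-homoscedastic in relative terms
over the fitted range. Optional residual-resampling bootstrap standard
errors (200 replicates by default) cross-check the OLS ones;
`constrain_nonnegative` clips a negative coefficient to zero and refits the
nested model.

## The synthetic stated world

`gen_bench_measurements()` emulates the steady bench rig: for each
set-point flow and replicate, observed flow is $\dot V(1+\varepsilon_f)$
and observed drop is $\Delta p(\dot V)(1+\varepsilon_p)$ with independent
Gaussian relative errors of SD 0.6% (flow meter) and 0.5% (pressure
transducers) — the instruments' accuracy specs read as 1-SD relative
Gaussian noise, the conventional simulation interpretation. The default
sweep is 20 evenly spaced flows over 1–60 L/min (the validity range of the
quadratic laws; the actual bench set points are unpublished) with 10
replicates, i.e. 200 records per restrictor, matching the published
campaign size. Generators are pure functions of (parameters, seed).

`gen_wall_profile()` emulates a sectioned-part microscopy trace:
$r(z) = (D_{nom} - u)/2 + (A/2)\sin(2\pi z/\ell) + \mathcal N(0,\sigma)$
for undersize $u$, diameter-scale feature size $A$ and layer thickness
$\ell$, on a grid of 16 samples per layer over a 2.5 mm span (a typical
throat length; ≥ 4 layer periods for all common layer heights, ≥ 8 samples
per period). What it does **not** emulate: aperiodic print defects, blobs
and stringing, ovality, or axial taper — so a green round-trip test
establishes that the estimators recover periodic-ridge-plus-offset
structure at microscopy precision (±0.01 mm), not that they are robust to
every real print pathology.

## Print-tolerance conventions

`summarize_profile()` reports the mean internal diameter (twice the mean
radius), the peak-to-peak of a low-pass diameter trend (a one-layer-period
moving average removes ridge texture so it is not double-counted into
bore-size variation), the ridge feature size, the I.D.-error-to-layer
ratio $(D_{nom} - \bar D)/\ell$, and the fourth-power pressure inflation
factor. The published ratio column for this metric is internally
inconsistent with its own name (e.g. a row with a 0.31 mm error over 50 µm
layers prints 2.4 where the formula gives 6.2), so we implement the
stated-name formula and do not assert the printed ratios.

`feature_size_fourier()` detrends the radius trace, finds the spectral peak
within ±30% of the layer frequency $1/\ell$, and reports the component's
amplitude on the **diameter** scale (twice the radius amplitude, matching
the magnitude convention of the published feature-size column). The
amplitude is estimated by a least-squares sinusoid fit at the best
frequency in the band rather than from the raw FFT bin, which removes
spectral-leakage bias and is exact for a pure sinusoid; the FFT peak is
still required to exceed 3× the median spectral floor, otherwise the
profile is declared ridge-free (0, with a warning).

`pressure_deviation_from_undersizing()` folds ridge roughness into an
effective diameter $D_{eff} = D_{meas} - 2k\,A_r$ (radius-scale amplitude
$A_r$): the ridges thicken the turbulent boundary layer, hydrodynamically
equivalent to a few percent diameter loss. No quantitative value for $k$
is established anywhere we know of, so it defaults to 1 (the geometric
floor of the ridge troughs) and is exposed as a parameter.

## Known ambiguities and limitations

* **Compliance labels.** The reference parameter table assigns the larger
  compliances to the restricted/"healthy" port, while the results table
  labels the restricted port $C = 0.1$ and the unrestricted port $C = 0.2$
  with opposite adjectives. The API therefore takes compliances explicitly
  per branch; `default_scenario()` follows the results-table values
  (restricted 0.1, unrestricted 0.2).
* **No CFD.** Published end-tidal volumes, waveform figures and flow-field
  imagery come from a ~3500-CPU-hour finite-volume simulation driven by an
  untabulated empirical inlet recording. This package is the lumped
  surrogate built around the CFD-fitted restrictor laws; its volume-level
  outputs agree with those tables qualitatively (ordering, monotonicity),
  not numerically, and the tests assert exactly that.
* **Mean resistances.** The published per-diameter mean resistances
  (156/51/25) imply time-average flows that were never printed; only the
  bare-splitter value 0.22 is independently checkable, and it checks out.
* **Single breath, inspiration only.** No cyclic steady state, one-way
  valves, leaks, humidity or gas-composition effects.
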