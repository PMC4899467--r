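---
title: "Methods: tree-ring isotope physiology, biomass increment and period contrasts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tree-ring isotope physiology, biomass increment and period contrasts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ringphys)
```

ringphys implements a retrospective analysis of conifer physiology under
atmospheric pollution. This vignette is the package's own account of the
models it fits, the conventions and numerical choices behind them, what
the synthetic-data generator does and does not emulate, and the known
limitations.

## The physiological model

Wood δ¹³C integrates the balance between stomatal CO₂ supply and
photosynthetic demand over the years a ring segment grew. The package
converts bulk-wood δ¹³C to foliage values through the empirical linear
relation δ¹³C_f = 1.0523 δ¹³C_w − 0.205 and expresses it as
discrimination against the contemporary atmosphere,

$$\Delta^{13}\mathrm{C} = \frac{\delta^{13}\mathrm{C}_{air} -
\delta^{13}\mathrm{C}_{f}}{1 + \delta^{13}\mathrm{C}_{f}/1000},$$

the standard Farquhar–Ehleringer form. Two printed variants of this
equation circulate with broken parenthesisation; the form above is the
one under which the boundary behaviour of the downstream equations is
coherent, and it is what the package computes. Referencing each segment
to the atmosphere of its own years absorbs the anthropogenic δ¹³C_air
decline (Suess effect), so discrimination is comparable across a century.

Intercellular CO₂ and intrinsic water-use efficiency follow from the
simple (mesophyll-free) discrimination model with a = 4.4 ‰ (stomatal
diffusion), b = 27 ‰ (carboxylation) and the CO₂/H₂O diffusivity ratio
0.625:

$$C_i = C_a\,\frac{\Delta - a}{b - a}, \qquad
\mathrm{iWUE} = (C_a - C_i)\cdot 0.625 .$$

At Δ = a the model pins C_i to zero, at Δ = b to C_a; measured values
slightly outside [a, b] yield C_i outside [0, C_a] and are kept with a
warning rather than clipped, because silent truncation would bias period
means. Assumptions worth keeping in mind: no mesophyll conductance term,
no post-photosynthetic fractionation beyond the fixed wood–foliage
offset, and A = (C_a − C_i)·g_c.

**Atmosphere at segment scale.** A 1–5-year segment needs one δ¹³C_air
and one C_a. The package evaluates both at the arithmetic midpoint year
by linear interpolation of the annual record (`atmosphere_at =
"midpoint"`); averaging the annual values over the segment
(`"mean"`) is exposed as an option and differs negligibly for ≤ 5-year
segments on a near-linear record. Extrapolation outside the record is an
error, never silent.

## Biomass reconstruction

Per tree and year, diameter is reconstructed as
D(t) = 1.096·(2 Σ_{y≤t} w_y + 2·pith offset) in mm. The 1.096 factor
converts the under-bark radial sum to over-bark diameter; it can be
re-estimated from paired reconstructed/taped diameters with
`bark_factor_calibration()` (zero-intercept least squares, pooled over
catchments — the data behind the published factor do not separate sites).
Height uses a cubic (Čertovo) or quadratic (Plešné) polynomial with the
1.3 m breast-height intercept; crown length uses one pooled power law,
since crown length contributes little to total biomass. Geometry is
re-derived from every year's reconstructed diameter, i.e. the height and
crown models are applied retrospectively per year.

Cambial age uses the pith rule: missing rings = pith distance divided by
the mean of the five innermost ring widths (rounded), plus 10 years for
growth from stump to coring height. Two printed formulations of this rule
("− 11" with ages counted from 1, "10 additional years" with an
inclusive count) reconcile to the same ages; the package implements
`pith_year = first_year − round(offset/mean5) − 10` with
`age(t) = t − pith_year + 1`.

The five component allometries are log-linear in ln(D/10), ln(height),
ln(age) and ln(crown length), each with a leading multiplier applied to
the whole linear predictor. Those multipliers resemble log-bias
corrections that are conventionally applied differently (to the variance,
outside the bracket), but the package evaluates the printed form exactly
— fidelity to the published models wins over convention. Diameter is mm
end-to-end; the division by 10 inside the biomass formulas (cm) is
internal. Annual increment is the first difference of total biomass;
negative increments (possible where the age terms dominate) are retained
and reported with a message, never dropped.

## Detrending

Increment series mix the signal of interest (inter-annual climate
response) with age trends, competition dynamics and slow climate drift.
The package removes the low-frequency part in two steps.

*Adaptive power transform.* The exponent p = 1 − m is estimated from the
pooled non-overlapping 10-year segments of all series, where m is the
least-squares slope of log₁₀(IQR) on log₁₀(median). The printed
description of this regression is directionally ambiguous; the
orientation used here is the one under which p = 1 − m reproduces the
classic variance-stabilisation rule (homoscedastic series → m ≈ 0 →
p ≈ 1; spread proportional to level → p near the 0.05 clip,
near-logarithmic) and the magnitude of the published estimate (p = 0.14).
The reverse orientation is available via `orientation =`. Trailing short
segments are dropped; zero-IQR segments are dropped with a warning; p is
clipped to [0.05, 1]. Whether the exponent is estimated from ring widths
or from biomass increments is configurable by what you pass in; the
pipeline uses increments, the quantity being detrended.

*Cutoff smoothing spline.* A cubic smoothing spline whose smoothing
parameter is chosen so that a sinusoid of 30-year period is attenuated to
50 % of its amplitude. Rather than hard-coding a parameter, the package
finds it by bisection (60 iterations on the log penalty) against the
amplitude transfer measured on the series' own time grid, with the
measurement window restricted to the interior (half a wavelength trimmed
at each end) because any smoother is less stiff at the boundaries. The
result is deterministic, cached per grid, and reproduces the 0.5 transfer
within a few percent for any series long enough (≥ wavelength/2 points).
The residual index is transformed minus spline — subtraction, not
division. Climate series pass through the same spline step but with
p = 1: a power transform of temperature (which crosses 0 °C) is
undefined, so "the same procedure" is interpreted as spline-only for
climate.

## Growth–climate correlations

The month screen correlates the mean detrended chronology with each of
the 24 candidate months (current + previous year) per variable over a
fixed window (default 1901–2007), using Spearman's ρ with two-sided
p-values from the asymptotic t approximation. The screen is exploratory;
no multiplicity correction is applied, and the output carries a
`multiplicity = "none"` attribute to make that explicit. The four default
seasonal windows (May–Sep temperature, May–Jul cloud, previous Jul–Sep
precipitation sum, previous-September PDSI) are the canonical choices for
cold-humid mountain spruce forests; previous-year months attach to the
ring year they influence.

Period correlations are computed per tree × variable × period (not on the
mean chronology): the period mixed models operate on tree-level values,
so the correlations feeding them must be tree-level too. Periods with
fewer than 5 overlapping years are flagged missing rather than computed.
Running correlations default to a centred 31-year window (an odd window
of roughly a generation; the source analysis does not state one).

## Period contrasts

Values are averaged into one number per tree and period: plain means for
annual series, year-overlap-weighted means for segment variables (a
segment half inside a period counts half). The model is
`value ~ period (+ catchment ± interaction) + (1 | tree)`. Candidate
fixed structures — intercept-only, period, period + catchment,
period × catchment, each optionally with a covariate — are compared by
maximum-likelihood AIC (the intercept-only candidate makes the selection
honest under a true null), and the winning structure is refitted by REML
for the reported estimates, the convention under which fixed-structure
AIC comparison is valid. Reference levels are the earliest period and the
Čertovo catchment. Singular random-effect fits fall back to ordinary
least squares with a warning.

Tukey pairwise comparisons use single-step adjustment on model marginal
means (emmeans); the compact letter display is computed by an
insert-and-absorb assignment that is transitive-consistent with the
p-value matrix by construction. Marginal/conditional pseudo-R² follows
the variance-partition definition for Gaussian random-intercept models:
R²m = var(fixed)/(var(fixed)+var(random)+var(residual)), R²c adds the
random-intercept variance to the numerator.

`percent_change_report()` is exact arithmetic on a coefficient table:
predictions are intercept + period term (+ catchment term + interaction
if present), percent changes are rounded to integers and absolute
differences to one decimal — the printing convention of the case study.
Two conventions matter and are deliberate: an absent non-reference
main-effect term is an error ("not estimated in the best model"), while
an absent interaction contributes zero (dropping an interaction asserts
additivity); and the baseline for "recent increase" statements is the
pollution-period (1971–1989) prediction, the only baseline consistent
with the published catchment-specific percentages. The published
narrative mixes baselines for the C_i trajectory (pre-period for the
first post-pollution window, pollution-period for the second); the report
emits both under explicit names. Decimal commas in coefficient CSVs are
accepted, as is common in continental-European tables.

## The synthetic-data generator

The field data behind the case study are not deposited, so the package
ships a generator that reproduces the *statistical structure* the
analysis assumes — it is a first-class, tested module, not a fixture.

* **Atmosphere**: deterministic exponential C_a(t) = 293.84 +
  2.158·exp((t−1850)/42.86), solved once so that C_a(1850) = 296 ppm and
  the 1971–1989 / 2006–2011 period means are 339 / 381 ppm (the
  case-study anchors); δ¹³C_air declines linearly in C_a from −6.4 to
  −8.3 ‰.
* **Climate**: monthly temperature = 4 °C annual mean + 9 °C seasonal
  cosine + a weak linear trend + year-level (SD 0.6) and month-level
  (SD 1.5) noise; gamma monthly precipitation summing ≈ 1230 mm yr⁻¹
  with wetter summers; cloud cover negatively coupled to the temperature
  anomaly; PDSI as an AR(1) accumulation (φ = 0.85) of standardized
  precipitation anomalies.
* **Ring widths**: width = (3·e^(−0.015·age) + 0.4 mm) ·
  exp(tree level + 0.15·z_T + AR(1) noise), with z_T the standardized
  May–Sep temperature shared by all trees, AR coefficient 0.90 and
  innovation SD 0.15, tree-level SD 0.25, pith offsets uniform on
  [0, 10] mm. These values were calibrated once so the realized
  chronology descriptives sit at the published magnitudes (mean
  sensitivity ≈ 0.20, lag-1 autocorrelation ≈ 0.87); an AR coefficient
  of 0.85 — the more conventional default — leaves the autocorrelation
  visibly short of the published 0.86–0.88.
* **Isotopes**: annual Δ¹³C = 19.635 + period effect (the published
  estimates −1.876/−0.696/−0.480 ‰) + tree intercept (SD 0.57) + annual
  noise (SD 1.15), inverted through the discrimination and wood–foliage
  relations into 1–5-year wood δ¹³C segments. Effects are injected on the
  Δ scale because that is where the inference lives; the inversion uses
  the segment-mean Δ and midpoint atmosphere so the reconstruction is
  exact in the noiseless case. The two SDs were derived from the
  published R²m/R²c (≈ 0.52/0.87) via the variance-partition identity,
  accounting for the averaging of annual noise into periods of 36/19/8/6
  years.

What the generator does **not** emulate: cross-dating error, locally
absent rings, disturbance pulses and competition release, wood-density
variation, juvenile isotope effects, segment-boundary misalignment with
calendar years, and any real coupling between growth and discrimination
(the increment–Δ model is validated on directly constructed data
instead). Passing tests therefore demonstrate that the machinery recovers
known structure of this idealized kind, not that any particular field
dataset would yield the published estimates.

## Numerical conventions and edge cases

* Ring widths of exactly 0 are legal (missing rings) and propagate; a
  width of 9.99 mm cannot be written to Tucson format because the value
  999 is the stop marker, and the writer refuses rather than corrupt.
* Mean sensitivity skips zero-sum pairs with a warning and errors when
  all pairs degenerate; it is bounded in [0, 2] and scale-invariant.
* Lag-1 autocorrelation of a zero-variance series is NA with a warning.
* All year fields are inclusive calendar years; a ring dated Y formed in
  the growing season of year Y.
* Isotope segments may overlap within a tree (warned, not rejected): the
  source protocol does not guarantee contiguity.
* The spline cache keys on (length, spacing, wavelength, response), so
  repeated detrending of same-grid series calibrates once.

## Problem sizes

The test suite and acceptance script run the generator at its default
sizes (210 increment trees and 31 isotope trees over 1850–2011) for the
calibration checks, 200 replicates of 31 trees × 4 periods for
mixed-model coverage, 400 segments for the power-recovery simulation,
300-point series for the spline transfer, and ~2000 replicates for the
Spearman null calibration — sizes chosen to make the Monte-Carlo
tolerances (±0.03 on p and on the spline transfer, ±2 % on AR recovery)
comfortably resolvable.

## Limitations

The physiological chain inherits every assumption of the simple
discrimination model; iWUE is *intrinsic* (per unit conductance), not a
water-use measurement. The allometric models are specific to Norway
spruce in the two catchments; applying them elsewhere changes the
constants, not the code paths. Period contrasts assume the period
partition is exogenous (defined by the deposition history, not by the
data). And because the original measurements are not public, the
published coefficient tables are treated as authoritative inputs for the
report arithmetic rather than re-derived from raw data.
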