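# ringphys

Retrospective dendro-physiological analysis of conifers under atmospheric
pollution: reconstruct tree physiology and biomass growth from tree rings,
detrend, correlate with climate, and contrast pollution-defined calendar
periods with mixed-effect models.

The package was built around a case study of mountain Norway spruce
(*Picea abies*) in two glacial-lake catchments of the Bohemian Forest
(Čertovo, Plešné), where acid sulfate/nitrogen deposition peaked in the
1970s–1980s. It is aimed at dendroecologists and stable-isotope plant
ecophysiologists who want the whole chain — from raw Tucson ring-width
files and wood δ¹³C segment tables to period contrasts — as tested,
reusable functions.

## What it computes

**Isotope physiology.** Bulk-wood δ¹³C is mapped to foliage
(δ¹³C_f = 1.0523·δ¹³C_w − 0.205) and expressed as discrimination against
the contemporary atmosphere,

Δ¹³C = (δ¹³C_air − δ¹³C_f) / (1 + δ¹³C_f/1000)  [‰],

with δ¹³C_air and Ca linearly interpolated from an annual (ice-core-style)
record at each segment's midpoint year. From the simple Farquhar model,

Ci = Ca · (Δ¹³C − a)/(b − a),  a = 4.4 ‰, b = 27 ‰,
iWUE = (Ca − Ci) · 0.625  [μmol CO₂ mol⁻¹ H₂O].

**Biomass increment.** Ring widths (plus estimated pith offset) are
cumulated to over-bark diameter D(t) = 1.096·(2·Σw + 2·pith), converted to
height and crown length through site polynomials, to cambial age through
the pith/stump-age rule, and to five biomass components (needles,
branches, dry branches, stem, roots) through published log-linear
allometries. The annual increment is the first difference of total
biomass; inter-annual variability is the classic mean sensitivity
s_t = 2|x_t − x_{t−1}|/(x_t + x_{t−1}).

**Detrending.** Increment series are power-transformed with the adaptive
exponent p = 1 − m, where m is the slope of log₁₀(IQR) on log₁₀(median)
over non-overlapping 10-year segments, then a cubic smoothing spline with
a 50 % frequency cutoff at 30 years is subtracted (the smoothing parameter
is found by bisection on the measured amplitude transfer, so the criterion
holds for any series length).

**Growth–climate correlations.** Monthly climate is screened month by
month (current and previous year) against the mean increment chronology,
aggregated into the four canonical seasonal windows (May–Sep temperature,
May–Jul cloud cover, previous Jul–Sep precipitation, previous-September
PDSI), and correlated per tree and period with Spearman's ρ; running
correlations display temporal stability.

**Period contrasts.** Every physiological variable is averaged into one
value per tree and pollution-defined period (pre 1900–1935, pollution
1971–1989, post 1998–2005 and 2006–2011; segment variables weighted by
year overlap) and modelled with `lmer(value ~ period (+ catchment) +
(1|tree))`. Candidate fixed structures are compared by ML AIC, estimates
come from the REML refit, Tukey single-step comparisons give compact
letter displays, and Nakagawa-style marginal/conditional pseudo-R² is
reported. `percent_change_report()` turns any coefficient table into the
headline percent changes; the published case-study tables ship with the
package (`reference_coefficients()`).

**Synthetic data.** Because the original field data are not deposited, a
calibrated generator (`sim_config()`, `simulate_*()`) reproduces the
statistical structure of the study: age-trended AR(1) ring widths sharing
a summer-temperature signal (mean sensitivity ≈ 0.20, lag-1
autocorrelation ≈ 0.87), δ¹³C segments with period effects and tree
random intercepts at the published magnitudes, a smooth anthropogenic
Ca/δ¹³C_air record (339 ppm in 1971–1989, 381 ppm in 2006–2011), and
seasonal mountain climate. `run_pipeline()` chains everything.

## Worked example

```r
library(ringphys)

atm <- data.frame(year = 1970:1976,
                  d13c_air = c(-7.28,-7.30,-7.32,-7.33,-7.35,-7.37,-7.39),
                  ca_ppm = c(325.7,326.3,327.5,329.7,330.2,331.1,332.0))
seg <- data.frame(tree_id = "CER01", start_year = 1971, end_year = 1975,
                  d13c_wood = -24.1)
physiology_series(seg, atm)
#>   tree_id start_year end_year d13c_wood d13c_foliage delta13C ci_ppm   iwue
#> 1   CER01       1971     1975     -24.1      -25.565   18.714 208.82 75.551
```

A 5-year segment with wood δ¹³C of −24.1 ‰, referenced to the 1973
atmosphere (δ¹³C_air −7.33 ‰, Ca 329.7 ppm), discriminates by 18.71 ‰,
implying an intercellular CO₂ of 209 ppm and an intrinsic water-use
efficiency of 75.6 μmol CO₂ mol⁻¹ H₂O.

```r
s <- ring_width_series("CER01", "Certovo", 1901,
                       c(2.31, 2.02, 1.87, 1.95, 1.71, 1.60, 1.48, 1.52),
                       pith_offset_mm = 3)
biomass_series(s)[1:4, c("year","diameter_mm","height_m","age",
                         "total_kg","increment_kg")]
#>   year diameter_mm height_m age total_kg increment_kg
#> 1 1901       11.64    2.299  13   0.2230           NA
#> 2 1902       16.07    2.674  14   0.4706       0.2476
#> 3 1903       20.17    3.018  15   0.7863       0.3157
#> 4 1904       24.44    3.375  16   1.2070       0.4207

rep <- headline_report()
rep$delta13c_pollution_change_pct   # -10 (% change pre -> pollution)
rep$iwue_pollution_increase_pct     #  40 (% change pre -> pollution)
```

The report arithmetic assembles period predictions from the bundled
coefficient tables (intercept + period + catchment + interaction terms)
and prints the percent change between periods — here the 10 % drop in
discrimination during the pollution peak and the concurrent 40 % jump in
water-use efficiency.

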