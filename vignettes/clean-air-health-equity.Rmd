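---
title: "Attributable burden, gain of life expectancy, and the geographic equity of cleaner air"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attributable burden, gain of life expectancy, and the geographic equity of cleaner air}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question

Staged air-pollution-control programmes — such as China's two-stage clean
air actions over 2013–2020 — reduce ambient PM2.5 while ozone may first
rise and later fall. Two questions follow: how large is the resulting
health benefit, and how evenly is it shared across the population's
geography? `glequity` implements the full assessment chain for both
questions: a risk-assessment model of the mortality burden attributable to
long-term PM2.5 and ozone exposure on a population grid, its translation
into per-capita life-expectancy metrics, and a population-weighted
Lorenz/Gini analysis of where the benefits landed. Because the 1-km
national input surfaces behind such assessments are not redistributable,
the package ships a fully synthetic, seed-reproducible scenario generator
whose defaults emulate the national two-stage trajectory; every stage of
the pipeline is exercised and tested against it.

## The burden model

For grid cell $s$, year $t$ and sex × age-band × residence subgroup $k$,
attributable deaths are

$$D_{s,t,k} = \mathrm{AF}(C_{s,t}) \times B_{s,k} \times P_{s,t,k},
\qquad \mathrm{AF} = 1 - 1/\mathrm{RR},$$

where $C$ is the annual-mean PM2.5 (or the peak-season ozone metric), $B$
the baseline cause-specific mortality rate and $P$ the subgroup
population. The relative risk comes from a tabulated nonlinear
exposure–response curve normalized at the theoretical minimum-risk
exposure level (TMREL):

$$\mathrm{RR}(C) = \frac{\mathrm{curve}(\max(C, \mathrm{TMREL}))}
{\mathrm{curve}(\mathrm{TMREL})},$$

evaluated by linear interpolation between concentration knots, clipped to
1 below TMREL, and held flat beyond the last knot. Linear (rather than
log-concentration) interpolation preserves monotonicity and makes results
bit-reproducible; the clip encodes the convention that no protective
effect is counted below TMREL, so attributable fractions are never
negative. Six causes of death carry a PM2.5 curve (ischemic heart
disease, stroke, lung cancer, COPD, lower-respiratory-tract infection,
type-2 diabetes; the cardiovascular pair age-band-specific), and COPD
carries the single all-adult ozone curve.

Deaths are weighted by residual life expectancy $LE_k$ into years of life
lost, and rescaled per capita into loss of life expectancy:

$$\mathrm{YLL}_{s,t} = \sum_k D_{s,t,k} LE_k, \qquad
\mathrm{LLE}_{s,t} = LE_0 \, \mathrm{YLL}_{s,t} / P_{s,t}.$$

$LE_0$, life expectancy at birth, is a free scaling constant (default
77.6 y, a contemporary Chinese value); it cancels out of benefit *shares*
and the Gini index, and rescales LLE/GLE linearly. Every output header
records it.

The health benefit of a control stage from year $y_1$ to $y_2$ is the
**gain of life expectancy**

$$\mathrm{GLE}_s = \mathrm{LLE}_{s,y_1} - \mathrm{LLE}_{s,y_2},$$

with the population-adjusted years of life gain derived as
$\mathrm{YLG}_s = \mathrm{GLE}_s P_{s,y_2} / LE_0$, so the identity
$\mathrm{GLE}_s P_{s,y_2} = LE_0 \mathrm{YLG}_s$ holds exactly. A derived
form of the stage-benefit definition that circulates in the literature
carries the population ratio $P_{y_1}/P_{y_2}$ inside YLG, which is
algebraically inconsistent with the LLE-difference definition; this
package treats the LLE difference as primary and derives YLG from it
(consistency requires the ratio the other way up), rather than silently
resolving the discrepancy the other way.

The combined PM2.5 + O3 burden is the **sum** of the two pollutants' LLE.
Epidemiological evidence for a positive PM2.5 × O3 interaction exists, in
which case separately estimated burdens are not strictly additive and the
additive combination is conservative for synergic control; the package
documents rather than models this.

## Exposure metrics

* Long-term ozone exposure uses the peak-season metric: the maximum
  6-month moving average of the 12 monthly means of the daily 8-h average
  concentration. Windows do not wrap across calendar years, giving exactly
  seven candidate windows per year; whether cross-year windows (e.g.
  Nov–Apr) should be admitted is genuinely ambiguous, and the within-year
  convention was chosen because all other metrics here are per calendar
  year. The operator is exposed directly as
  `peak_season_concentration()`.
* Exceedance fractions use a strict inequality — cells exactly at the
  threshold count as compliant.
* Per-cell trends are ordinary least-squares slopes on calendar year;
  population weighting uses $\sum C_s P_s / \sum P_s$; direct
  standardization weights stratum rates by a fixed reference structure
  (conventionally the first study year).

## Inequality: Lorenz curves and the Gini index

Treating per-capita GLE as "health income", cells are sorted by GLE
ascending (ties broken by cell id for reproducibility) and the Lorenz
curve plots cumulative population share against cumulative share of the
total benefit $\sum \mathrm{GLE}_s P_{s,y_2}$, reported at every cell
boundary (the exact polygonal curve, not binned). The Gini index is one
minus twice the trapezoid area under the curve; for non-negative benefits
it coincides with the population-weighted mean-absolute-difference form,
and the test suite verifies the two routes against each other to 1e-10 on
a thousand random instances. The axis convention is the standard one
(population share horizontal); the Gini index is invariant under exchanging
the axes, so either orientation yields the same summary.

Cells with *negative* GLE — places where pollution worsened between the
stage endpoints, as peak-season ozone did in parts of the emulated
first stage — are included by default, sorted first; the curve can then
dip below zero and the Gini index may exceed 1. The result carries
`n_negative_cells` and a warning; `negatives = "drop"` removes them with
an explicit message instead. Both behaviours are exposed because the
convention is not settled; inclusive is the default so that no benefit
mass is silently discarded.

Uncertainty intervals are *not* produced for Lorenz/Gini outputs by
default; recomputing the full spatial burden per draw is the expensive
path, and the package mirrors the practice of reporting the inequality
metrics as point summaries. An experimental `lorenz_uncertainty` flag in
`run_config()` computes draw-wise Gini indices anyway for those willing
to pay.

## Monte Carlo uncertainty

Exposure–response uncertainty is propagated by recomputing any national
metric once per curve draw and reporting empirical percentile intervals
(`stats::quantile()` type 7 — linear interpolation between order
statistics, pinned so intervals are bit-reproducible). The default is 100
draws for desk-scale runs; 1000 is recommended for production runs.
Intervals reflect exposure–response uncertainty only (optionally plus
TMREL sampling, below); baseline-rate and exposure-field uncertainty are
not modelled. The central estimate uses the central curve, so draws are
expected to bracket it; the interval constructor warns (not errors) if
they do not.

TMREL handling: fixed per curve by default (PM2.5 4.15 µg/m³, the
midpoint of the conventional 2.4–5.9 uniform band; ozone 64 µg/m³). With
`tmrel_sampling = TRUE` each draw samples its own TMREL uniformly from
the configured interval and the draw's relative risk is re-normalized at
that level — the tabulated curve itself is unchanged, only the reference
point moves, which is the standard way the minimum-risk uncertainty is
carried.

## The synthetic scenario generator

The generator is first-class, tested code, not a fixture. What it
emulates, per component:

* **Exposure fields.** Spatial structure comes from smoothing white noise
  with an isotropic Gaussian kernel (bandwidth `spatial_corr_length`,
  default 4 cells) and re-standardizing — the simplest controllable
  autocorrelation. PM2.5 starts at a population-weighted ~69 µg/m³
  (spatial sd 20 µg/m³, chosen so that ~96% of the population starts
  above the 35 µg/m³ standard, matching the emulated setting) and
  declines stage-wise by the configured mean fractions
  (default 31.7% then 24.1%, reproducing the national 68.98 → 47.13 →
  35.77 µg/m³ trajectory) with smooth cell-level heterogeneity. The
  default heterogeneity is larger in stage 1 than stage 2, emulating the
  more even, multi-region improvements of the later programme. Ozone
  starts near 111 µg/m³ peak-season and shifts additively (+9.7 then
  −6.2 µg/m³): a rise, then a partial fall. Negative concentrations from
  additive noise are truncated at zero and counted.
* **Monthly ozone.** The peak-season level times a July-peaking sinusoid
  normalized so its own peak-season metric is exactly 1 — this keeps the
  peak-season operator non-trivial while making the generated level
  recoverable, a deliberate recovery hook. One seasonal profile is shared
  by all cells; real seasonal phase varies with latitude, which the
  generator does not attempt.
* **Population.** Per-cell totals follow a smooth log-normal density
  field normalized to a constant national total (default 1.09 billion
  adults). Subgroup counts factorize into an age-pyramid share (5-year
  bands 25 to 95+), a sex share, and a per-cell urban/rural split drawn
  smoothly within `urban_fraction_range`. The pyramid tilts olderward
  each year at `aging_rate` (default adds roughly a quarter of a year of
  population-weighted mean age per calendar year, a rapid-aging setting).
* **Mortality.** A Gompertz age schedule (rates doubling about every 8
  years of age) with sex and residence multipliers, calibrated so the
  first-year crude adult rate is 7.6 per 1000. Cause-specific rates are
  the all-cause rate times a fixed cause profile (with an explicit
  `other` remainder, so cause rates sum exactly to all-cause — a
  conservation the tests assert). The schedule is year-invariant:
  secular mortality decline (falling age-specific rates from better
  healthcare) is *not* emulated, so the standardized rate is constant
  across years while aging still raises the raw crude rate. Residual life
  expectancy follows a smooth concave decline consistent with
  aspirational reference life tables used for YLL accounting.
* **Exposure–response curves.** The family
  $RR(C) = 1 + \alpha(1 - e^{-\beta \max(0, C-\mathrm{TMREL})^\gamma})$
  with $\gamma < 1$ gives the sublinear shape characteristic of PM2.5
  risk curves: the same µg/m³ of improvement buys more health at a lower
  baseline. Draws perturb $(\alpha, \beta)$ log-normally (default
  log-scale sd 0.1), so every draw stays ≥ 1 and monotone. The default
  magnitudes were calibrated once so that the default scenario's
  first-year national burden matches the scale of the emulated setting
  (PM2.5 loss of life expectancy near 1.86 years; ozone YLL near 1.76
  million); the curves are synthetic stand-ins valid on their tabulated
  range, not estimates of any published curve.

**What passing tests do and do not show.** The generator produces smooth
Gaussian-kernel fields, a separable population structure, and a
parametric risk family. Real exposure surfaces have sharp urban
gradients, terrain effects and correlated errors; real populations do not
factorize by cell × age × sex × residence; real risk curves carry
correlated draw uncertainty from meta-regression. Tests passing on this
scenario validate the *computational chain* — metrics, burden
aggregation, equity analysis, uncertainty propagation — not any
substantive epidemiological claim about real data.

## Numerical choices

* Concentration tables use a 0.5 µg/m³ knot step by default; against the
  closed-form family this keeps interpolation error well under 1e-2, and
  a 0.05 step brings it under 1e-3 (the property the tests check on a
  dense grid).
* Lorenz ties are broken by cell id; sorting is stable, so repeated runs
  are identical.
* Aggregations use exact summation over strata; the brute-force loop
  oracle in the test suite reproduces national YLL to 1e-9 relative on
  the full 50 × 50 default grid.
* Degenerate inputs fail loudly and specifically: zero total population,
  all-zero benefit (Lorenz undefined — the pipeline records the skip in
  its manifest rather than fabricating a curve), missing months in a
  monthly series (no imputation), missing strata (error names the cell,
  year and subgroup).
* Cell ids are row-major from the north-west corner; the run manifest
  records the convention. Gridded outputs are long tables (plus a
  `field_matrix()` helper); no georeferenced raster export is provided.

## Problem sizes

The default scenario is a 50 × 50 grid, three years, 15 age bands, 100
curve draws — the scale at which the package's own acceptance checks run
end-to-end in minutes on one core. Module tests use 10 × 10 grids; the
generator-recovery check uses 100 × 100 (10,000 cells) so the realized
stage reduction can be compared against its configured value within
sampling tolerance. All sizes are configurable.

## Known limitations

* Burden additivity across pollutants ignores interaction (above).
* The year-invariant mortality schedule understates changes in
  vulnerability over time; stage-wise gains in settings with rapidly
  falling baseline mortality will differ in magnitude from this
  scenario's.
* No decomposition of the Gini index by subgroup, and no socioeconomic
  stratification: the analysis is purely geographic.
* Curves are inputs; the package does no meta-regression and cannot
  validate curve shapes against any external source.
* Exposure upstream of monthly means (daily 8-h averages, dasymetric
  population mapping, exposure prediction models) is out of scope.
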