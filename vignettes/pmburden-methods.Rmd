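---
title: "Methods: gridded excess mortality from PM2.5 and its carbonaceous fraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gridded excess mortality from PM2.5 and its carbonaceous fraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmburden)
```

# The model

`pmburden` estimates the annual number of adult deaths attributable to
long-term exposure to fine particulate matter (PM2.5) on a regular grid, and
apportions that burden to emission sectors and to the anthropogenic
carbonaceous fraction of the aerosol (aCA: black carbon plus primary and
anthropogenic secondary organic aerosol).

For every grid cell, cause of death $j$, and adult age class $k$,

$$
M_{\mathrm{PM2.5}}(x, y) \;=\; \sum_{j,k}
  \mathrm{BMR}\big(c(x,y),\, j,\, k\big)\;
  \mathrm{POP}(x, y, k)\;
  \mathrm{AF}\big(\mathrm{RR}_{jk}(C(x,y))\big),
$$

where $C$ is the annual-mean PM2.5 concentration (µg/m³), $\mathrm{BMR}$ the
country-level baseline mortality rate (deaths · person⁻¹ · yr⁻¹) broadcast to
cells through a country mask $c(x,y)$, $\mathrm{POP}$ the population per cell
and age class, and $\mathrm{AF} = (\mathrm{RR}-1)/\mathrm{RR}$ the
attributable fraction. Six causes are considered — ischemic heart disease
(IHD), stroke, COPD, lung cancer, lower respiratory infections and type II
diabetes — over twelve 5-year age classes from 25–29 to 80plus. Risk is
age-dependent for IHD and stroke (one curve per age class); the other causes
use a single curve applied to each age class with age-specific BMR and POP,
because the sum over $(j,k)$ requires per-age terms even when RR is
age-invariant. Child mortality (< 5 yr LRI) is out of scope.

The carbonaceous-aerosol burden multiplies the total-PM2.5 mortality by the
local mass ratio,

$$
M_{\mathrm{aCA}}(x,y) = M_{\mathrm{PM2.5}}(x,y)\,
  \min\!\Big(1,\; \tau\,\frac{\mathrm{aCA}(x,y)}{\mathrm{PM2.5}(x,y)}\Big),
$$

with toxicity weight $\tau = 1$ (equal toxicity) or $\tau = 2$ (carbonaceous
particles assumed twice as toxic as other PM2.5). The two-fold assumption is
implemented literally as a doubling of the fractional contribution with the
total PM2.5 toxicity held constant: RR is never re-evaluated at inflated
concentrations, and the weight is capped at 1 so attributed deaths can never
exceed the total. A useful consequence, exercised by the test suite, is that
whenever the mass fraction stays at or below one half, the two-fold
attribution is exactly twice the equal-toxicity attribution.

## Exposure–response functions

Two risk-curve families are supported behind one interface:

* **Tabulated curves** (`tabulated_erf`): RR at ascending concentration
  knots with central / low / high branches, consumed as knot tables in the
  way spline-based meta-regression output (e.g. the GBD MR-BRT curves) is
  distributed. Curves are anchored at the theoretical minimum risk exposure
  level (TMREL, default 4.15 µg/m³, the mean of the 2.4–5.9 µg/m³ uniform
  distribution): each branch is divided by its own interpolated value at the
  TMREL and RR is set to exactly 1 at and below it. Evaluation is
  piecewise-linear between knots — monotonicity-preserving, and the knot
  density can be made arbitrarily fine — with constant extrapolation beyond
  the last knot.
* **GEMM-style parametric curves** (`gemm_params`): the four-parameter
  logistic-log form
  $\mathrm{RR}(z) = \exp\{\theta \log(1+z/\alpha)\,/\,(1+e^{-(z-\mu)/\nu})\}$
  with $z = \max(0, C - C_0)$, used as a sensitivity risk model. The
  counterfactual $C_0$ defaults to the same 4.15 µg/m³ as the tabulated
  TMREL so the two families are directly comparable; the original 2.4 µg/m³
  can be set per parameter row.

Uncertainty is propagated as whole curves: the low/high branches are treated
as the bounds of the 95% interval and carried through every downstream
computation (bound propagation). For the GEMM family the branches use
$\theta \mp 1.96\,\mathrm{se}(\theta)$. This is a deliberate, simple choice;
it does not sample TMREL or baseline-rate uncertainty, so reported intervals
reflect risk-curve uncertainty only and need not match intervals produced by
Monte-Carlo propagation.

## Sectoral attribution and the linearity diagnostic

A sector's contribution is estimated by zero-out differencing: mortality
under the full-emission baseline minus mortality under a scenario with the
sector's emissions removed (100%) or reduced (20%). Negative cell
differences — possible in principle where chemistry responds non-linearly —
are retained, not clipped, and counted in a diagnostic attribute.

Whether differencing is a fair attribution method depends on the
concentration response being close to linear in the removed emissions. The
diagnostic computes, per cell,
$r = 5\,(C_{\mathrm{BASE}} - C_{20\%}) / (C_{\mathrm{BASE}} - C_{100\%})$,
which is identically 1 for a linear response; cells where the 100%-removal
signal is below `eps` (default 0.01 µg/m³, configurable) carry no
information and are excluded and counted. The summary is the unweighted mean
of $r$ over valid cells.

# Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `tmrel` | 4.15 | µg/m³ | no-excess-risk threshold anchoring all curves |
| toxicity factors | 1, 2 | – | aCA mass-fraction reweighting |
| `eps` (linearity) | 0.01 | µg/m³ | minimum sectoral signal per cell |
| regrid method | bilinear | – | concentrations; nearest for categorical rasters |
| health grid | 5 km cells | km | calculation resolution (model fields regridded to it) |

Grids are cell-center registered, row-major with the origin at the
lower-left cell center, all axis-aligned in one planar projection — the
simplest unambiguous convention. Regridding of intensive quantities
(concentrations) is bilinear; mass-conservative regridding is unnecessary
for intensive fields. Each health-grid cell belongs wholly to one country;
no fractional border cells. Population weighting uses the total adult
population by default, with an `ages` argument to restrict the weight basis.

# The synthetic-data generator

Real inputs of this kind of assessment — chemical-transport model fields,
gridded census population, national burden tables — are large external
datasets. The generator reproduces their *statistical structure* so the
entire pipeline runs and is testable offline:

* **Sector fields.** Each sector (residential `RES`, road transport `TRA`,
  `OTHER`, and a broad `BACKGROUND`) contributes a smooth non-negative
  surface: a Gaussian kernel mixture centered on shared city locations with
  a per-sector correlation length, scaled to the sector's amplitude. The
  sector's aCA field is a fixed mass share of its PM2.5 — residential 0.45,
  transport 0.25, other 0.10, background 0.02 by default, reflecting the
  carbon-rich character of combustion sectors. These defaults place
  countrywide aCA/PM2.5 fractions at roughly 4–23% and population-weighted
  BASE PM2.5 at about 3–21 µg/m³, the ranges typical of wider Europe;
  they are illustrative, not calibrated to any particular year.
* **Scenario composition.** A scenario removing fraction $r_s$ of each
  sector is $C = \sum_s (1-r_s)\,C_s + \gamma\,I$, where the interaction
  $I = (\sum_s (1-r_s) C_s)^2$, normalized by its full-emission domain
  maximum, emulates non-linear secondary-aerosol chemistry. The interaction
  is intentionally *quadratic* in the composed total: any pairwise product
  of distinct sector fields would be linear in each sector's retained
  fraction and would cancel exactly in scenario differences, leaving the
  linearity diagnostic blind to it. With $\gamma = 0$ composition is exactly
  additive — differencing recovers each sector field identically and the
  diagnostic equals 1 in every valid cell — while increasing $\gamma$ moves
  the diagnostic away from 1 monotonically, which is what the property
  tests exercise.
* **Population** follows the city-kernel surface raised to a clustering
  exponent with multiplicative log-normal noise, zero on the sea margin,
  scaled to the requested total and split over the twelve age classes with
  an old-skewed, European-like structure (constant shares across cells).
* **Country mask**: nearest-seed (Voronoi) partition of the land cells into
  contiguous blocks, with synthetic codes `XA`, `XB`, … from a code range
  without real-world assignments.
* **Baseline rates**: per-cause base rates drawn within plausible ranges,
  multiplied by a Gompertz-like exponential age gradient and a per-country
  level factor; coverage is complete over countries × causes × ages.
* **Curves**: the saturating form $\mathrm{RR}_{\mathrm{raw}}(C) = 1 + a\,
  (1 - e^{-C/s})$, tabulated at fixed knots and TMREL-anchored — monotone,
  concave (supralinear) over 0–30 µg/m³ like the cause-specific curves it
  emulates — with low/high branches at $0.7a$ and $1.3a$, and risk
  declining with age for the age-dependent causes.

Everything is a deterministic function of the spec's single seed (offset
sub-seeds per component, applied with `withr::with_seed` so the caller's RNG
state is untouched).

What passing tests on synthetic data do *not* show: the generator has no
meteorology, seasonality, chemical speciation beyond the PM2.5/aCA pair, or
realistic inter-country rate contrasts, so agreement on synthetic fixtures
validates the computational contract of the pipeline, not the realism of any
particular burden estimate.

# Numerical choices

* Accumulation is in double precision throughout; stored results and all
  intermediate tables are unrounded. Rounding happens only in
  `render_report`: domain death totals to the nearest thousand, per-country
  deaths to the nearest integer, and percentages rounded half-away-from-zero
  (`share_percent`).
* Cells with PM2.5 = 0 get an aCA fraction of 0 (with a warning) and the
  fraction is clamped to [0, 1], keeping the attribution total on empty
  cells; sea cells contribute zero mortality regardless of concentration.
* Zero total population in a country makes a population-weighted mean
  undefined and raises an error rather than returning 0.
* Degenerate single-row or single-column source grids reduce bilinear
  interpolation to 1-D linear interpolation along the remaining axis.
* Rasters and tables are stored as plain text (a self-describing header plus
  a full-precision `%.17g` matrix body, and CSV for tabular data), so every
  write–read round trip is exact and artifacts are diffable and portable.

# Problem sizes

The default synthetic study is a 60 × 60 grid of 5-km cells with 4 countries
and 8 cities; the full five-scenario pipeline (6 causes × 12 ages × 3
uncertainty branches per scenario) completes in a few seconds, and the
complete test suite — including brute-force cell-by-cell oracle comparisons
on 8 × 8 grids and the 60 × 60 sector-recovery and linearity properties —
runs in well under a minute.

# Known limitations

* Bound propagation understates or misstates interval asymmetry relative to
  resampling approaches; intervals are risk-curve-only.
* Attribution of the `OTHER` sector is the residual total − RES − TRA; no
  finer source split, and no emission-species-level attribution.
* Fixed-value TMREL only; the uniform TMREL distribution is not sampled.
* No map reprojection: all grids must share one planar projection, and
  regridding is interpolation, not area-weighted conservation.
* Morbidity, years of life lost and age-standardized rates are out of scope.

```{r}
study <- generate_study(synthetic_spec(seed = 7))
report <- run_pipeline(study)
report
```
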