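---
title: "Scoring historical redlining and modelling longitudinal air pollution trends"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring historical redlining and modelling longitudinal air pollution trends}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(redlinair)
```

## The problem

In the 1930s the Home Owners' Loan Corporation (HOLC) graded urban
neighbourhoods A ("best") through D ("hazardous", drawn in red). Those maps
codified disinvestment patterns whose legacy is still measurable: historically
redlined areas tend to hold more pollution sources and poorer residents today.
`redlinair` implements the tract-level analysis pipeline used to study this
legacy longitudinally: score modern census tracts by their historical HOLC
coverage, attach annual PM2.5/NO2 exposures from a gridded daily surface,
summarise demographic and Social Vulnerability Index (SVI) gradients by score
category, and model pollution levels and trends with a linear mixed model.

Because the original inputs (digitized HOLC shapefiles, census geometry,
proprietary exposure surfaces) are large downloads, the package ships a
synthetic-city generator with known ground truth; every stage of the pipeline
is exercised and calibrated against it.

## The redlining score

For tract $i$ with land area $a_i$, let $a_{ig}$ be the area of the tract
covered by HOLC grade $g \in \{A, B, C, D\}$. With numeric grades
$w_A, \dots, w_D = 1, \dots, 4$, the continuous score is

$$ s_i = \sum_g \frac{a_{ig}}{a_i}\, w_g \in [0, 4], $$

binned right-closed: $(0,1] \to$ A, $(1,2] \to$ B, $(2,3] \to$ C,
$(3,4] \to$ D, and $s_i = 0 \to$ *ungraded*. Tracts enter the analysis when
they intersect the convex hull of the graded polygons with positive area.

Design choices where the published rule is silent:

* **Tract selection** uses positive-area intersection (default sliver
  tolerance 1 m^2^); tracts sharing only an edge with the boundary are
  excluded. This is a documented choice, not an inferred intent.
* **Interval endpoints** are right-closed, so a score of exactly 1.0 is
  category A, matching the "> 0–1" notation of the source grading rule.
* **No minimum graded-fraction threshold**: any positive overlap above the
  sliver tolerance makes a tract graded.
* **Denominator**: the score divides by *land* area (taken from the tract
  attribute when supplied, e.g. census `ALAND`; else from the polygon), while
  exposure weights divide by total polygon area — the two conventions the
  respective methods use.
* **Overlapping graded polygons** (digitization artifacts) can push the
  fraction total above 1; fractions are then rescaled to sum to 1 with a
  data-quality warning.

### Geometry engine

All geometry lives in one projected planar frame in metres; the package does
no coordinate-reference-system handling, so real-data users must supply
layers in a common equal-area projection. Overlay is computed exactly with a
small planar toolkit (shoelace areas, convex hulls, Sutherland–Hodgman
clipping). Intersection requires at least one convex operand — always true
for the rectangles and hulls the package produces, and for real data this
means tract polygons should be convex or pre-decomposed; arbitrary
concave-with-concave overlays are out of scope.

## Exposure aggregation

Each tract's daily value is the area-proportional weighted average of the
grid cells overlapping it: $w_{ig} = |T_i \cap C_g| / |T_i|$. Choices:

* **Coverage shortfall**: raw weights sum to the covered fraction. When
  coverage is at least 0.8 (configurable) weights are renormalized to sum
  to 1; below that the tract-day is treated as missing.
* **Annual means** average the non-missing days of a calendar year (leap days
  included) and are reported missing when fewer than `min_day_frac = 0.75` of
  the year's days are available. The completeness rule is a package default;
  the source analysis assumed complete surfaces.
* **Cells missing on a given day** are dropped and the remaining weights
  renormalized for that day.

### Screening aberrant values

Real exposure surfaces can carry sustained clusters of implausible values
(for example a two-year stretch of aberrantly low NO2). Two screens are
provided:

* `manual_list` removes exactly the configured (cell, date-range) tuples, so
  an inspection-based published exclusion is exactly expressible in
  configuration.
* `robust_z` flags cell-days whose value deviates from the cell's
  same-calendar-month median across all years by more than `threshold`
  (default 5) robust SDs, sustained for at least `min_run_days` (default 14)
  consecutive calendar days. The robust SD is the *within-month day-to-day*
  scale — the median across years of each year-by-month scaled MAD. Using the
  across-year MAD instead would fold the annual trend into the scale and
  blind the screen to shifts of realistic size; with the within-month scale,
  a slow annual trend widens deviations by at most half the trend span while
  the scale stays at the daily-noise level.

Screening already-clean data removes nothing. One caveat: after screening an
actually contaminated grid, a second pass can flag residual aberrant days the
first pass missed at the detection margin, because removing the bulk of a
cluster sharpens the robust statistics. The screen is conservative in the
other direction: deviations are never flagged when the within-month MAD is
zero (a noise-free surface).

## The trend model

Annual mean exposure $y_{it}$ for tract $i$ in year $t$ with score category
$c(i)$ is modelled as

$$ y_{it} = \beta_0 + \beta_{c(i)} + (\beta_t + \beta_{tc(i)})\,(t - t_0)
          + u_i + \varepsilon_{it}, \qquad
   u_i \sim N(0, \sigma^2_u), \quad
   \varepsilon_{it} \sim N(0, \sigma^2_e), $$

with the reference category (default A) absorbed into $\beta_0, \beta_t$ and
$t_0$ the first panel year, so the intercept is the reference-category level
in that year. Choices:

* **Estimation** is REML via `lme4`, falling back to maximum likelihood when
  REML fails to converge cleanly (the fallback is recorded in the fit
  metadata). Random structure is a tract random intercept; random slopes are
  deliberately not fitted by default.
* **Noise-free panels** ($\sigma_u = \sigma_e = 0$) make the mixed-model
  likelihood degenerate; `fit_trend` detects an essentially zero
  least-squares residual and returns the exact least-squares solution with
  zero variance components. This is what allows exact parameter-recovery
  tests against the generator truth.
* **Overall tests** of category level differences at a year (testing all
  $\beta_c + \beta_{tc}(t - t_0) = 0$ jointly) and of slope differences
  (all $\beta_{tc} = 0$) are Wald chi-square tests on the fitted fixed-effect
  covariance. Denominator-degrees-of-freedom corrections
  (Satterthwaite/Kenward–Roger) are out of scope; in the package's
  calibration studies the resulting type-I error runs slightly above nominal
  (about 0.06 at $\alpha = 0.05$ for the study sizes simulated) but inside
  the accepted 0.03–0.07 band.
* **Pairwise contrasts** of each non-reference category versus the reference
  use normal Wald statistics with a Bonferroni threshold $\alpha/m$, where
  $m$ is the number of non-reference categories actually present (4 when an
  ungraded category exists, 3 otherwise). By default contrasts are only
  evaluated when the corresponding overall test is significant at $\alpha$
  (gating), mirroring standard practice.
* Each pollutant is fitted in its own model. The trend table orders
  categories D, C, B, ungraded, reference.

## The synthetic city

The generator emulates exactly the statistical structure the analysis
assumes, with known truth:

* **Tracts**: an $n_x \times n_y$ lattice of square tracts (default 1 km),
  `land_area` equal to polygon area.
* **HOLC map**: non-overlapping grade rectangles on a half-tract lattice so
  graded polygons split tracts; a seeded random subset of half-cells stays
  ungraded (`margin`), and grades fill the rest in contiguous serpentine runs
  sized to target fractions (realized coverage is exact up to half-cell
  rounding). Expected overlap fractions are analytically computable, which is
  what the exactness tests exploit.
* **Pollution**: each cell inherits the category of its dominant tract and
  generates daily values as level + linear annual trend + one annual sinusoid
  + tract random intercept + Gaussian daily noise. Default NO2 magnitudes:
  category levels 31.7–35.7 ppb at the first year, slopes −1.01 to −0.82
  ppb/yr; PM2.5 defaults are 15.6–16.2 μg/m^3^ and about −0.5 μg/m^3^/yr.
* **Daily noise**: the within-year variance of real daily surfaces is not
  published; the default `noise_sd = 1.5` (with `tract_re_sd = 0.5`,
  seasonal amplitude 3) is chosen for testability — large enough to exercise
  the screens and the mixed model, small enough that a −15-unit injected
  aberration is unambiguous (about 10 robust SDs). These defaults are fixed
  study conditions, not tuning knobs.
* **Census/SVI tables**: tract values drawn from category-specific normal
  distributions per period, sized to the familiar redlining gradients of a
  large US city (income, home value, college attainment highest in A;
  poverty and percent Black highest in D; D-category SVI roughly twice A);
  percentages clamped to [0, 100] and SVI to [0, 1]; missingness injectable.

What the generator does *not* emulate — street networks, population
synthesis, satellite/meteorology predictors, spatially correlated residuals,
non-sinusoidal seasonality — bounds what passing tests show: they validate
the overlay arithmetic, the aggregation algebra, the screening behaviour and
the mixed-model inference under the assumed structure, not the fidelity of
any upstream exposure model.

## Simulation study sizes

The package's calibration checks use: 500-replicate studies with 100 tracts
per category over 17 years ($\sigma_u = 0.5$, $\sigma_e = 0.3$) for slope-CI
coverage (accepted band 93–97%), 30 tracts per category for null type-I
error (band 0.03–0.07), ten seeded replicates of a 25-cell six-year grid for
screening recovery (at least 90% of injected cell-days flagged, under 1%
false positives), and a $10^5$-point Monte-Carlo point-sampling oracle for
area-weighted aggregation (agreement within 3 Monte-Carlo SEs). These sizes
are the package's chosen study conditions and are fixed in the acceptance
suite.

## Known limitations

* No CRS handling, no shapefile reader: geometry interchange is GeoJSON in a
  projected planar metre frame.
* Overlay needs one convex operand per intersection; highly concave tract
  polygons must be pre-processed.
* Category means are unweighted tract averages (no population weighting);
  percent change is computed on category-level means, not averaged
  tract-level changes.
* No spatial correlation between tracts and no autoregressive residuals in
  the trend model; no small-sample df corrections for the Wald tests.
* The aggregation is area-weighted, not population-weighted, and no
  interpolation of missing cells is attempted.

## A worked example

```{r example, eval = FALSE}
city <- simulate_city(nx = 8, ny = 8, years = 2000:2008, seed = 1)
city$scores                       # category counts and shares
panel <- aggregate_city(city$tracts, city$pollution)
tt <- build_trend_table(panel, city$scores, years = c(2000, 2004, 2008))
tt                                # predicted levels, slopes, starred contrasts
summary_tabs <- build_summary(city$census, city$svi, city$scores)
head(format_summary(summary_tabs)$census)
```
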