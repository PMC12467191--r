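---
title: "Methods: burden trends, inequality indices, and frontier analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: burden trends, inequality indices, and frontier analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibroburden)
```

# Scope and data model

fibroburden analyses country-year-cause panels of disease-burden estimates in
the layout of GBD results-tool exports: one row per location, year, cause,
measure (deaths or DALYs), metric (rate, number, or percent) and age
aggregation (age-standardized or all-age), with a 95% uncertainty interval
around each value. Age-standardized rates (ASR, per 100,000) are taken as
given inputs; the package never re-standardizes, because that would require
age-specific counts and a reference population that exports of this shape do
not carry. The socio-demographic index (SDI, a composite development score in
[0, 1]) and population enter through separate tables joined by location name,
since SDI and population files in circulation frequently lack location ids;
an id column is carried through when present but is never required.

Everywhere an ordering of countries matters - midpoint ranks, concentration
curves, panel slices, deviator tables - countries are sorted by ascending SDI
with ties broken by location name. The tie-break has no epidemiological
content; it exists so that every computation is a deterministic function of
its inputs.

# Change statistics and cause shares

`relative_change(v0, v1)` is `100 (v1 - v0) / v0` and `percent_decline` its
exact negative; both refuse a zero baseline, where the quantity is undefined.
Cause shares (`cause_proportion`) are computed from all-age *number*-metric
records - person or person-year totals summed over locations - never from
rates, because a share of a rate has no population interpretation. Shares are
therefore invariant under any uniform rescaling of the counts.

Group-level summary tables (`summary_table`) consume pre-aggregated rows
named "Global", "High SDI", ..., "Low SDI" rather than pooling countries:
aggregating age-standardized rates across countries correctly requires
age-specific data outside this data model. For synthetic panels,
`sdi_group_rates()` emits compatible rows using population-weighted means
within population-share quintile bands - an approximation that is clearly
labelled as such and used only where synthetic group rows are needed. The
package ships one fixture, `table1_rates()`, transcribing published GBD 2021
age-standardized death and DALY rates for neoplasms and COPD by SDI group in
1990 and 2021; the test suite reproduces all the percent-change statements
derivable from it at two decimals. All internal arithmetic is full precision;
`present_round()` (round half away from zero, two decimals, the convention of
printed tables) is applied only at the reporting layer. Two published
companion figures are knowingly not reproducible from their own inputs - a
mortality-share rise printed as 4.83% where the quoted shares give 4.85%, and
a tuberculosis decline exceeding 100% of the baseline - and are therefore
excluded from the exact-reproduction surface.

# Slope index of inequality

Countries are ranked by SDI and each receives the population-weighted
midpoint of its interval on the cumulative population-share axis:
`midpoint_rank_i = cum_before_i + pop_share_i / 2`. The SII is the fitted
slope of the ASR on this rank, so its units are the indicator's units across
the full rank span (rank 0, least developed, to rank 1, most developed); a
negative SII means burden concentrated at the low-SDI end.

Two estimators are exposed because "robust linear regression" admits several
readings and nothing in the published description pins down the estimator
family or weighting:

* `method = "wls"` (default): least squares with population-share weights,
  so each country counts in proportion to the population it represents on
  the rank axis. This is the estimator whose closed form the tests verify.
* `method = "huber"`: a Huber M-estimator (tuning constant 1.345, the
  standard 95%-efficiency choice) with the same weights, for panels with
  outlying countries. On outlier-free data the two agree within 1%, which
  the suite checks by construction.

Uncertainty intervals come from a seeded nonparametric bootstrap: countries
are resampled with replacement, midpoint ranks are re-derived *within each
resample* (ranks are sample statistics, not fixed covariates), and the
percentile interval of the refitted slopes is reported; 1000 replicates by
default. The published SII values carry 95% intervals without a stated
method, so the bootstrap - assumption-light and reproducible under a seed -
is the package's documented choice.

# Concentration index of inequality

With countries in ascending SDI order, country `i` contributes burden share
`rate_i * pop_i / sum_j rate_j * pop_j` - per-capita rates are converted to
totals so "cumulative proportion of DALYs" means what it says. The
concentration curve joins (0, 0) to the cumulative (population share, burden
share) points, and

```
CII = 1 - 2 * integral_0^1 L(p) dp
```

by the trapezoid rule over exactly those points: no smoothing, no grouping;
countries are the atoms of the curve. Positive values indicate burden
concentrated in high-SDI countries, negative in low-SDI countries, zero when
all rates are equal. Two exact symmetries follow from the construction and
are tested: the index is invariant under scaling of all rates, and reversing
the SDI order flips its sign exactly (the curve rotates 180 degrees about
(1/2, 1/2)). Values always lie in [-1, 1]. Erreygers/Wagstaff
normalizations and index decompositions are deliberately out of scope.

# Frontier analysis

The frontier is the minimum ASR empirically achievable at a given SDI. A
locally weighted regression through a point cloud is not by itself a
minimum, so the package uses a transparent lower-envelope construction:

1. pool all country-years (1990-2021 by default, per-year fitting available
   via the `years` argument of `frontier_points`);
2. partition the observed SDI span into `n_bins` equal-width bins (default
   100) and take the minimum ASR in each occupied bin, placed at the bin
   midpoint;
3. smooth the minima with locally weighted linear regression (tricube
   weights, `span = bandwidth`, default 0.3);
4. clamp the smoothed curve at each bin to that bin's observed minimum and
   floor it at zero.

The clamp guarantees the envelope property - no observed point lies below
the frontier within its bin beyond interpolation error - so every "effective
difference" `max(0, observed - frontier)` is non-negative by construction.
`clamp = FALSE` gives the pure smooth through the minima for sensitivity
checks. Defaults were set so each local fit rests on enough occupied bins at
the intended panel scale (about 204 countries by 32 years); when a small
input occupies fewer bins than the span can support, the effective span is
widened to cover at least four bins and recorded in the returned object. No
monotonicity in SDI is imposed - the published description does not state
one - and evaluation is linear interpolation on the occupied-bin-midpoint
grid with no extrapolation: records outside the fitted span are flagged and
excluded per record rather than failing the run. Deviator rankings break
ties alphabetically; the top-15 convention and the low-SDI/high-SDI exemplar
lists (cutoffs 0.45 and 0.80, both configurable) mirror the labelling of
frontier scatter plots.

# Synthetic panel generator

`generate_panel` draws panels with exactly the structure the analyses
assume, so every stage is testable offline against known truth:

* **SDI paths**: per-country linear growth with jittered start (uniform on
  [0.05, 0.85]) and slope (normal, mean 0.006/yr, sd 0.003, floored at 0),
  clipped to [0, 1] - the simplest monotone path satisfying the bounds. Real
  SDI trajectories saturate; a logistic model was rejected as adding
  parameters no test needs.
* **Burden**: `ASR = g(SDI) + delta_c + eps` with frontier
  `g(s) = max(0, a + b s)`, one-sided exponential country offsets `delta_c`
  (so the frontier is a true lower envelope, matching the premise of a
  minimum achievable rate), and Gaussian noise truncated at `-delta_c` so no
  observation beats its frontier. Default intercepts and slopes sit in the
  range of published GBD 2021 ASRs for the six causes (DALY rates in the
  hundreds-to-thousands per 100,000, death rates in the tens-to-hundreds);
  deaths and DALYs use independent parameter sets because the analyses never
  link them mechanistically. Default noise_sd is 10 rate units - visible
  against death rates, mild against DALY rates.
* **linear_gradient mode** generates ASR linear in the population-weighted
  midpoint *rank* rather than raw SDI. This is deliberate: the SII is defined
  on the rank scale, so only a rank-linear truth makes "the regression
  recovers the generating slope" an exact statement (to floating-point
  precision) rather than an approximate one.
* **Bookkeeping**: number-metric records are `rate * population / 1e5`; an
  "All causes" total per location-year is the cause sum times an inflation
  factor (default 6, placing the six-cause share near 1/6 of total burden,
  in the vicinity of published fibrosis-related shares); uncertainty
  intervals are +/-10% bands with no propagation semantics. Randomness runs
  through per-component sub-streams derived from the single spec seed, so
  regenerating one component cannot perturb another.

What the generator does *not* emulate - real country SDI trajectories, real
burden magnitudes per country, age structure, correlated uncertainty - means
passing recovery tests demonstrate the estimators are correct on data
satisfying their assumptions, not that the published headline values are
reproduced. Those values (SII 1507.98 to 328.00 for neoplasms, CII -0.16 to
-0.20 for COPD, the named frontier countries) are functions of the real GBD
2021 panel, which users must download themselves; the readers accept such
exports directly.

# Numerical choices and problem sizes

Degenerate inputs fail loudly and early: zero baselines for change
statistics, fewer than three countries or all-zero rates for the indices,
fewer than three occupied bins for the frontier, duplicate burden keys at
panel assembly. CSV parsing rejects grouping separators rather than
silently misreading locale-formatted numbers, and panel CSVs are written at
17 significant digits so write-read round-trips are exact.

The test suite exercises full-size recovery (204 countries, 32 years,
noiseless) once, with bootstraps trimmed to 25-200 replicates elsewhere;
the whole suite runs in seconds. The acceptance script repeats the
full-size recovery and the fixture-derived worked examples from scratch at
its given seed. Pipeline runs are reproducible end to end: identical config
and seed yield identical output checksums, recorded per file in
`manifest.json`.

# Known limitations

* Group-level age-standardized rates cannot be derived from country rows
  within this data model; synthetic group rows use population-weighted
  means and are so labelled.
* The bootstrap treats countries as independent; spatial or temporal
  dependence between countries is not modelled.
* The frontier depends on bin width near the span edges, where minima rest
  on few points; conclusions about specific edge countries warrant a
  sensitivity pass over `n_bins` and `bandwidth`.
* Uncertainty intervals carried through tables are not propagated into
  change statistics, matching the published presentation, which reports
  none for them.
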