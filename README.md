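# fibroburden

Fibrotic remodelling is a common end-stage of several of the world's largest
causes of death and disability — neoplasms, chronic obstructive pulmonary
disease (COPD), chronic kidney disease, cirrhosis, hypertensive heart
disease, tuberculosis. Quantifying how that burden is distributed across
levels of socioeconomic development, and how far each country sits from the
best outcome empirically achievable at its development level, is the job of
this package. It is aimed at epidemiologists and health-policy analysts
working with GBD-style country–year–cause estimate tables (age-standardized
rates per 100,000 with 95% uncertainty intervals, an SDI table, a population
table).

## What it computes

With countries ranked by the socio-demographic index (SDI) and given
population-weighted midpoint cumulative ranks $R_i \in (0,1)$:

* **Slope index of inequality (SII)** — the fitted slope of the
  age-standardized rate $y_i$ on $R_i$ (population-weighted least squares by
  default, Huber M-estimation with $k = 1.345$ as the robust option), in rate
  units per full rank span; bootstrap percentile CIs over countries.
* **Concentration index of inequality (CII)** — with burden shares
  $w_i = y_i p_i / \sum_j y_j p_j$ and the concentration curve $L(p)$ through
  the cumulative (population share, burden share) points,
  $\mathrm{CII} = 1 - 2\int_0^1 L(p)\,dp$ by the trapezoid rule;
  negative when burden concentrates in low-SDI countries.
* **Frontier analysis** — the minimum achievable rate as a function of SDI,
  built as bin-minima → locally weighted linear smooth (tricube weights,
  span 0.3, 100 bins) → clamp to each bin's observed minimum; each
  country-year's *effective difference* is
  $\max(0,\; y - \mathrm{frontier}(s))$.
* **Trend statistics** — cause shares of all-cause burden from number-metric
  totals, percent changes and ratios of age-standardized rates, and
  Table-1-style group summaries.
* **Synthetic panels** — a seeded generator producing GBD-shaped panels
  (204 countries × 1990–2021 × six causes) with known frontier, known
  country inefficiency offsets and known gradients, so every estimator is
  tested against ground truth offline.

## Worked example

Published GBD 2021 group rates for neoplasms and COPD ship as a transcribed
fixture; the global COPD DALY decline falls straight out of it:

```r
library(fibroburden)
st <- summary_table(table1_rates(), years = c(1990, 2021))
st[st$group == "Global" & st$cause == "COPD" & st$measure == "dalys",
   c("value_start", "value_end", "percent_decline")]
#>    value_start value_end percent_decline
#> 19     1492.64    940.66        36.98012
```

i.e. the global age-standardized COPD DALY rate fell 36.98% between 1990 and
2021 (from 1492.64 to 940.66 per 100,000). On a synthetic panel, the full
inequality and frontier machinery:

```r
gen <- generate_panel(panel_spec(seed = 42))   # 204 countries, 1990-2021
ts <- inequality_timeseries(gen$panel, "Chronic obstructive pulmonary disease",
                            "dalys", years = c(1990, 2021),
                            n_bootstrap = 200, seed = 42)
ts
#>   year    sii sii_lower sii_upper      cii cii_lower cii_upper   n
#> 1 1990 -523.5     -1019      -240 -0.05153   -0.1024  -0.02408 204
#> 2 2021 -648.0     -1073      -326 -0.08008   -0.1272  -0.04022 204
```

The negative SII and CII say this (simulated) COPD-like burden is loaded
onto low-SDI countries — the generator's frontier slopes downward in SDI —
and the bootstrap intervals exclude zero in both years. The countries
furthest above the minimum-achievable frontier:

```r
pts   <- frontier_points(gen$panel, "Chronic obstructive pulmonary disease", "dalys")
gaps  <- effective_differences(fit_frontier(pts), pts)
rank_deviators(gaps, year = 2021, k = 3)$top
#>      location    sdi observed_asr frontier_asr effective_difference
#> 1 Country 097 0.3349         3874       1368.6                 2505
#> 2 Country 149 0.6207         2807        993.0                 1814
#> 3 Country 184 0.9835         2082        521.3                 1560
```

Each row is a country whose 2021 rate sits far above the frontier at its
SDI — its effective difference is the unrealized improvement potential in
rate units. `run_pipeline()` chains simulate → validate → trends →
inequality → frontier from one YAML/JSON config and writes a checksummed
`manifest.json`; real GHDx exports run through the same pipeline in `csv`
mode.

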