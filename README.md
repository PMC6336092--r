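# ceindex

Quantitative scoring of coastal ecosystem services for tidal-flat
assessments.

Restored and artificial tidal flats are monitored for years after
construction, and managers need to know three things per ecosystem
service: how good is the site now relative to comparable sites, where is
it heading, and — when it is heading down — which environmental factors
deserve countermeasures. `ceindex` implements a composite index in the
Ocean Health Index tradition that answers all three from ordinary
monitoring data: per-site indicator time series plus observed states of
the environmental factors in a user-declared conceptual model.

## The model

For each service *i* at each site, with indicator value *X* and
cross-site reference point *X<sub>R</sub>*:

- **Present status** — `x = X / X_R`, where `X_R` is the maximum retained
  indicator value across all compared sites over the most recent 5-year
  window. Pooled values beyond 2 sample standard deviations from the
  pooled mean are excluded as outliers before taking the maximum.
- **Trend** — `T = 5t`, clamped to [−1, +1], where *t* is the OLS slope
  of the normalized status over the window. Its 95% confidence interval
  is `5t ± 15·se` (the slope standard error scaled by an approximate
  3-degrees-of-freedom t multiplier of 3, then by the 5-year factor).
- **Pressure–resilience** — each environmental factor *j* scores
  `PR_ij ∈ [−1, +1]`: quantitative factors on a piecewise-linear model
  between two thresholds (e.g. dissolved oxygen: −1 at ≤ 2 mg/L, +1 at
  ≥ 6 mg/L), qualitative factors ±0.5 by presence/absence. `PR_i` is the
  (equal-weight) mean of the scored factors.
- **Near-term future status** — `x_F = (1 + βT + (1 − β)PR) · x`, with
  β = 0.67 weighting the measured trend 2:1 over the inferred PR score.
- **Service score** — `I = (x + x_F) / 2`, reported on a 0–100 scale.
- **Sustainability score** — `S = (x_F − x) / x`, reported as a percent;
  negative means the service decays under present conditions. Absent
  clamping, `S = βT + (1 − β)PR` exactly.

Negative-scoring factors behind a negative *S* are the countermeasure
targets; the package emits them as a digest and as per-cell radar-chart
data.

## Worked example

The packaged demonstration scenario emulates a four-site Tokyo-Bay-like
assessment (two artificial, two natural flats; six services; window
2009–2013):

```r
library(ceindex)
panel <- generate_panel(tokyo_bay_scenario(seed = 7))
a <- score_assessment(panel$config, panel$indicators, panel$factor_obs)
format_score_matrix(a)
#> # A tibble: 6 × 5
#>   service_id         SN        UK        TR        OR
#>   <chr>              <chr>     <chr>     <chr>     <chr>
#> 1 food               71.0/-24% 45.7/+19% 38.6/+5%  60.2/+16%
#> 2 coastal_protection 82.6/+20% 100.0/0%  70.1/-18% 85.6/+20%
#> 3 recreation         0.0/-     99.5/+1%  0.8/-5%   0.7/-5%
#> 4 research           66.4/+13% 12.9/+1%  100.0/0%  94.2/+13%
#> 5 suspended_removal  94.1/-8%  21.0/+21% 15.6/+16% 8.6/+1%
#> 6 diversity          81.6/-3%  99.9/0%   82.2/+9%  89.7/+26%
```

Each cell is `I/S%`: service score out of 100 and sustainability
percent. `71.0/-24%` for food at SN reads: high current quality relative
to the best compared site, but the service is projected to lose about a
quarter of its status over the next five years under present
conditions — so look at its factor scores. A dash marks an undefined
quantity (`0.0/-`: present status zero, sustainability undefined).

The full audit trail for any cell:

```r
explain_cell(a, "SN", "food")
#> Cell: site SN, service food (evaluation year 2013)
#> Window: 2009-2013; pooled observations: 19 retained, 1 excluded as outliers (k = 2)
#> ...
#> Reference point X_R = 28.48 (site SN, year 2010)
#> Present status: X = 22.96, x = X / X_R = 0.8061
#> Trend: slope t = -0.06348 per year, se = 0.01306, n = 4
#>   T = 5t (clamped to [-1, 1]) = -0.3174; 95% CI [-0.5133, -0.1216]
#> Factor scores:
#>   anoxic_water                  -0.4 (quantitative)
#>   ...
#> PR (weighted mean of scored factors) = -0.08125
#> Future status: raw (1 + 0.67 T + 0.33 PR) x = 0.6131
#> Service score I = (x + x_F) / 2 = 70.96 (percent100 scale)
#> Sustainability S = (x_F - x) / x = -0.2395 (-24%)
```

File-based runs write the complete report set (score matrix, tidy
scores, reference points, trend CIs, countermeasure digest, flag log,
radar CSVs):

```r
write_panel(panel, "demo_data")
run_assessment("demo_data/config.yaml", "demo_data", "demo_out")
```

or from a shell via the bundled CLI
(`inst/cli/cei.R validate|simulate|score|explain`).

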