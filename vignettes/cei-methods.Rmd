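---
title: "Scoring coastal ecosystem services: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring coastal ecosystem services: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ceindex)
```

## The assessment problem

Environmental improvement projects in coastal waters — artificial tidal
flats in particular — are small relative to the scales at which ecosystem
services are usually valued, change for years after construction, and are
managed against concrete questions: is each service the site provides
(food provision, coastal protection, recreation, water-quality
regulation, biodiversity, ...) at a good level compared with similar
sites, is it sustainable, and if not, which environmental factors should
countermeasures address? `ceindex` implements a relative, indicator-based
scoring framework for exactly this setting. It deliberately stops short
of valuation: scores are comparable across sites within one service, not
across services, and no weighting or monetary aggregation is attempted.

## The scoring model

All internal computation is on the unit scale; reporting multiplies by
100.

**Present status.** For service $i$, $x_i = X_i / X_{i,R}$, where $X_i$
is the raw indicator value in the evaluation year and the reference point
$X_{i,R}$ is the maximum *retained* indicator value pooled across all
compared sites over the window (default: the 5 most recent years,
including the evaluation year). This makes the assessment a relative
comparison among the compared sites — appropriate when artificial flats
are judged against natural flats in the same water body — rather than
against an absolute "best" state that stakeholders may not agree on. For
waters degraded long ago, a configuration hook accepts a fixed
user-supplied $X_{i,R}$ (e.g. an ideal pre-deterioration value) instead.

**Outlier screening.** Pooled values beyond $k$ sample standard
deviations from the pooled mean (default $k = 2$) are excluded from the
calculations. Three choices here were genuinely open and are resolved as
follows. (1) The sample over which the moments are computed is the pooled
per-service sample, all sites × all window years: pooling matches the
cross-site logic of the reference point, and a per-site window of 5
values could never yield an exclusion (the largest attainable sample
z-score at $n$ is $(n-1)/\sqrt n \approx 1.79$ at $n = 5$). (2)
Screening is single-pass — the moments are not re-estimated after
exclusion — as the conservative reading absent a stated iteration rule.
(3) An evaluation-year value that is itself screened out is barred from
being the reference point, but its normalized status is still computed
and flagged `OUTLIER_EVAL_YEAR` rather than blanked.

**Trend.** $T_i = 5\,t_i$ clamped to $[-1, 1]$, with $t_i$ the OLS slope
of normalized status on year over the window. The 95% confidence bounds
are $5 t_i \pm 15\,\mathrm{se}_i$: the slope standard error is scaled by
3 — a deliberate round approximation to the two-tailed $t$ quantile at
the three residual degrees of freedom of a five-point fit
($t_{0.975,3} = 3.18$), costing a point or two of nominal coverage — and
by the same factor 5 applied to the slope. We scale the slope and its
error *once*; the bounds are constructed around $5t_i$, not around an
already-scaled score. Bounds are clamped to $[-1, 1]$ and flagged when
clamping binds; whether to clamp was left open by the framework and we
clamp so that reported bounds live on the score's own scale. The trend
is fit on normalized status rather than raw values: the reference point
is constant within a window, so slope and standard error scale
identically and the clamp behaves consistently across services. With
fewer than `min_trend_points` retained years (default 3 — a two-point
fit has no error estimate) the trend is set to 0 and flagged
`NO_TREND_DATA`, the framework's missing-data rule.

**Pressure–resilience.** The conceptual model declares, per service, the
environmental factors of the surrounding natural and social systems that
influence it. Each factor scores in $[-1, 1]$ — negative as pressure,
positive as resilience:

* *Quantitative* factors use a piecewise-linear model between two
  thresholds set from prior research and criteria. Dissolved oxygen is
  the canonical case: $-1$ at $\le 2$ mg/L, $+1$ at $\ge 6$ mg/L, linear
  between, so the pressure/resilience boundary falls at 4 mg/L. A
  `decreasing_good` direction mirrors the line for quantities where less
  is better; none of the shipped examples need it, but the conceptual
  model framework does.
* *Qualitative* factors (blue-tide occurrence, ground stability,
  existence of management, ...) score $\pm$ a configurable magnitude,
  default 0.5: a condition only judged present/absent is provisionally
  assumed to carry half the influence of a measured one. An `unknown`
  state is excluded from aggregation rather than scored 0 — no
  information is not evidence of neutrality.

$PR_i$ is the weighted mean of the scored factors, with weights
defaulting to 1 (equal influence); the weight field anticipates future
differential weighting without changing present behavior. A service with
no evaluable factors (the shipped scenario's research service) carries
$PR = \mathrm{NA}$, and the projection falls back to $PR = 0$ with flag
`PR_DEFAULTED`, so its sustainability score reflects the recent trend
alone. By default factors are scored from their evaluation-year state;
`pr_years = "window"` averages factor scores over the window instead.

**Projection and scores.** The likely near-term future status is
$x_{i,F} = (1 + \beta T_i + (1-\beta) PR_i)\,x_i$ with $\beta = 0.67$ by
default, weighting the directly measured trend 2:1 over the indirectly
inferred PR score. The service score is $I_i = (x_i + x_{i,F})/2$ (0–100
on the default reporting scale) and the sustainability score is
$S_i = (x_{i,F} - x_i)/x_i$, undefined (reported as a dash) when the
present status is zero. Absent clamping these compose to the identity
$S_i = \beta T_i + (1-\beta) PR_i$, which the pipeline asserts at
run time; so $|S_i| \le 1$ always.

**Clamping the projection.** The multiplier lies in $[0, 2]$, so
$x_{i,F}$ can exceed the reference ceiling. We clamp it at 1 and flag
`CLAMPED_FUTURE`, keeping every reported score within 0–100; the raw
value is retained alongside so users can see when the clamp binds. This
is a package design decision: the framework does not state the behavior
above the ceiling, and published four-site score tables contain cells
(e.g. $I = 100$, $S = +54\%$) whose implied $x_F$ exceeds 100, so the
un-clamped convention also has precedent. The identity above is asserted
only where no clamping occurred.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `window_years` | 5 | years | matches the near-term projection horizon; both use the same window |
| `beta` | 0.67 | – | trend vs PR weight 2:1; measured change is trusted twice as much as inferred pressure |
| `outlier_k` | 2 | sd | the 2-sigma screening rule |
| `min_trend_points` | 3 | points | below 3 the slope error is undefined; trend defaults to 0 |
| `qualitative_magnitude` | 0.5 | score | provisional half-influence assumption for presence/absence factors, per factor |
| factor thresholds | e.g. DO 2/6 mg/L | factor units | from prior criteria; configuration, never estimated from data |

## The synthetic generator

`scenario_spec()`/`generate_panel()` produce complete assessment inputs
with known ground truth: per (site, service) a linear mean trajectory
$X_0 + \text{slope}\,(t - t_0)$ with Gaussian observation noise
truncated at zero (indicator values are non-negative quantities;
truncation slightly biases series whose mean sits within a few sd of
zero), plus multiplicative outlier shocks (uniform 4–8×) at a configured
rate, plus deterministic factor trajectories/states. Ground truth
(true slopes, noise-free statuses and reference points, true factor and
PR scores, the implied sustainability score) is computed directly from
the scenario arithmetic, independent of the scoring pipeline, and is
emitted alongside the data files.

The packaged `tokyo_bay_scenario()` emulates a four-site enclosed-bay
assessment — two artificial and two natural flats, six services with
mixed per-unit-area and whole-site indicators, window 2009–2013.
Baseline levels and trends are set to plausible magnitudes for such a
monitoring program, observation noise at 10% of the baseline level, and
outlier injection at 5% per value; these are fixed properties of the
scenario, not tuning knobs.

What the generator does *not* emulate: autocorrelated or non-Gaussian
indicator noise, nonlinear trajectories (succession dynamics in young
artificial flats), year-to-year changes in factor states, or correlation
between indicator noise and factor states. Tests passing on this
generator therefore demonstrate correctness of the scoring arithmetic
and its statistical behavior under the stated model — not that the index
is robust to every pathology of real survey data.

Test and validation problem sizes are chosen to keep the default suite
fast while still statistically informative: the identity suite samples
10,000 unclamped score tuples; the screening oracle enumerates 300
random panels of up to 20 values; trend recovery uses 500 replicates of
a five-point series at signal-to-noise 2, checking unbiasedness within
3 Monte-Carlo standard errors and ≥ 90% interval coverage (the ×3
multiplier is an approximation, so nominal 95% is not expected exactly).

## Numerical and degenerate-input choices

* Reference-point ties break to the earliest year, then the smallest
  site id — stable provenance under reordering.
* A service whose retained values are all zero has no defined reference
  point; this is an error (`cei_reference_undefined`), not a silent NA,
  because every downstream quantity for the service is meaningless.
* NA propagates with explicit flags (`NO_DATA`, `X_ZERO`, ...) instead
  of being zero-filled; report cells print dashes.
* The composed-stage identity is asserted to $10^{-9}$ inside the
  pipeline as a structural self-check.
* Factor diagnostics sort ascending by score with lexicographic
  tie-break, so "worst first" is deterministic.

## Known limitations

* No cross-service aggregation or weighting; scores are not comparable
  across services and no total site score is produced.
* No trade-off analysis between services, and no autocorrelation or
  nonlinearity in the trend model.
* Factor thresholds are configuration; the package never estimates them
  from data.
* The Shannon–Wiener helper uses the natural log and applies no
  survey-effort correction; indicator values for all other services are
  ingested precomputed.
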