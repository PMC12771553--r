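---
title: "Daytime and nighttime heatwave indices and case-crossover impact estimation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Daytime and nighttime heatwave indices and case-crossover impact estimation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nightheat)
```

## The problem

Heatwaves harm health through two distinct channels: hot days (high Tmax)
and hot nights that deny physiological recovery (high Tmin). Humid episodes
compress the diurnal temperature range, producing nights that stay warm
even when days are unexceptional, so the two exposures are correlated but
not interchangeable. `nightheat` separates them: it builds daily *daytime*
and *nighttime heatwave indices* (HWIs) from Tmax and Tmin, estimates their
associations with daily health-event counts in a self-matched
case-crossover design, tests whether the two effects differ, and converts
the fitted coefficients into annual heatwave-attributable burden.

## Heatwave definition and the daily indices

For each location, thresholds are the 95th percentiles of daily Tmax and
Tmin pooled over all warm-season days (May–October by default) of a
30-year reference climatology. Quantiles interpolate linearly between
order statistics at position $h = (n-1)p + 1$ (`stats::quantile` type 7).
Pooling all season-days — rather than a day-of-year window — matches the
single warm-season percentile convention of the heatwave literature.

A heatwave is a maximal run of at least 2 consecutive days (3 or 4 in
sensitivity analyses) on which Tmax *or* Tmin is strictly above its
threshold ("exceeds" is read strictly; with continuous temperatures the
boundary has probability zero). Runs never cross a missing day or a season
boundary; seasons are processed independently per calendar year, and
missing days propagate as missing exposure rather than being imputed.

An event is *daytime-accentuated* when its cumulative excess Tmax
($\sum \max(0, T_{max}-thr)$ over event days) exceeds its cumulative
excess Tmin, otherwise *nighttime-accentuated*. An exact tie is assigned
to nighttime: ties have measure zero for continuous data, but the rule
must be deterministic.

On every day inside an event, the daytime HWI is
$\max(0, T_{max} - thr_{max})$ and the nighttime HWI
$\max(0, T_{min} - thr_{min})$; both are zero on all other days,
including isolated single exceedance days. Both indices are kept on every
event day regardless of the event's classification — a humid night inside
a daytime-accentuated event still carries its nighttime excess — because
the daily index measures intensity while the classification describes the
event as a whole. The classification feeds only the binary event-day flags
(`dhw_flag`, `nhw_flag`, never both set). Users who prefer the stricter
reading can set `zero_off_type = TRUE` in `compute_daily_hwi()` to zero
the off-type index.

## The case-crossover model

Each location-day belongs to the stratum of all days sharing its location,
calendar year, month and day of week (ISO convention, Monday = 1); every
stratum has 4 or 5 days that serve as mutual case and control days. This
time-stratified self-matching removes, by design, all confounders that are
stable within a month — demographics, socioeconomics, long-term and
seasonal trends, day-of-week patterns.

Counts are modelled as

$$\log E(Y_{it}) = \alpha_{s(i,t)} + \beta_1\,\mathrm{DHWI}_{it} +
\beta_2\,\mathrm{NHWI}_{it}$$

with one intercept per stratum. Zero-count days are materialized in the
panel: a count model with stratum intercepts needs the complete day grid,
not only days with events. The stratum intercepts are eliminated by
conditioning on stratum totals: given $\sum_t Y_{it}$, the within-stratum
counts are multinomial with day probabilities
$p_t = e^{x_t'\beta} / \sum_u e^{x_u'\beta}$, so the conditional
likelihood involves only $\beta$. The package maximizes it by
Newton–Raphson with step halving (relative log-likelihood change below
$10^{-10}$ or 100 iterations; exposures enter through a log-sum-exp
guard). The estimates coincide — to numerical precision — with a Poisson
fit carrying explicit stratum dummies, which the test suite verifies
against `stats::glm` on every small panel.

Strata with zero total count, or in which every design column is constant,
contribute nothing to the conditional likelihood and are dropped before
fitting; a model with no informative strata, or a rank-deficient centered
design, is reported as unidentifiable rather than silently fitted.

Overdispersion is handled quasi-likelihood style: the Pearson statistic
over informative strata divided by $n - S - p$ degrees of freedom ($S$
informative strata, $p$ exposure parameters) scales the covariance.
Following standard quasi-Poisson practice the factor is *not* floored at
1, so ${\hat\phi} < 1$ deflates standard errors; a configurable
`dispersion_floor` (set it to 1) is available for the more conservative
convention. Scaling never changes point estimates.

Effects are reported as the percent change in daily counts per 1 °C of
HWI, $(e^{\beta} - 1)\times 100$, with Wald 95% intervals and normal
p-values.

### Exposure forms

- **Linear** (`linear_hwi`, the main analysis): one coefficient per index.
- **Binary** (`binary_hw`): the event-day flags replace the indices; the
  coefficient is a per-event-day effect, which aggregates intensity — when
  mean event-day intensity exceeds 1 °C the implied per-event effect
  exceeds the per-degree effect.
- **Natural cubic spline** (`fit_spline_model()`): each index gets an
  `splines::ns` basis with two interior knots at the 10th and 50th
  percentiles of its distribution and boundary knots at 0 and the observed
  maximum, so the fitted exposure–response curve is exactly 0 at HWI = 0.
  Knots are placed over *heatwave-day* (positive) values by default: the
  full distribution is mostly zeros, and pooling them would collapse both
  knots to 0 (`knots_include_zeros = TRUE` restores the pooled reading).
- **Single-lag models** (`fit_lag_model()`, lags 0–6): the exposure series
  is re-joined at $t - k$ and refitted separately per lag, the most common
  reading of a lag analysis; rows whose lagged date falls before coverage
  are dropped. A mutually adjusted distributed-lag model is deliberately
  out of scope.
- A same-day relative-humidity covariate (`covariates = "rh"`) reproduces
  the humidity-adjusted sensitivity analysis.

## Heterogeneity between estimates

Two estimates $E_1, E_2$ with standard errors $SE_1, SE_2$ are compared
through $d = E_1 - E_2$, $SE_d = \sqrt{SE_1^2 + SE_2^2}$, and a two-sided
z-test. Comparisons are made on the percent-change scale (percentage-point
differences), the scale on which such contrasts are conventionally
reported; `se_from_ci()` recovers standard errors from printed 95%
intervals so published estimates can be compared directly. For subgroup
families, `bonferroni_adjust()` multiplies p-values by the family size
$m$ and caps at 1; $m$ — conventionally the number of non-reference levels
within one subgroup dimension — is recorded with every adjusted value
because the appropriate family is analysis-specific.

## Attributable burden

For each day and heatwave type, the fraction of counts attributable to
the exposure is $AF = 1 - e^{-\beta \cdot HWI}$ — the implicit
counterfactual is the same day with HWI 0 — and the attributable number is
$AF \times$ observed count. Daily numbers sum exactly to annual totals per
type, and the two types' point estimates add to the total. Negative
coefficients yield negative (protective) fractions, which are reported,
not truncated.

Confidence intervals use parametric Monte Carlo: $(\beta_1, \beta_2)$ is
drawn (default 1000 times) from a bivariate normal with the fit's
estimates and dispersion-scaled covariance via a Cholesky factor, annual
totals are recomputed per draw, and the 2.5th/97.5th percentiles are
reported. Drawing the pair jointly preserves the coefficients'
correlation in the total's interval. Draws are seeded and bit-reproducible.

## The synthetic-data generator

Real acute-care data of this kind are confidential, so the package ships
a generator that emulates the statistical structure the analysis assumes,
with known ground truth for every downstream check:

- **Tmax**: a seasonal sinusoid peaking in mid-July (level 28 °C,
  amplitude 6 °C) plus AR(1) anomalies (lag-1 correlation 0.7, marginal SD
  2.5 °C), independent across locations and seasons.
- **Humid episodes**: a two-state Markov chain (stationary frequency 0.15,
  day-to-day persistence 0.88) marks humid spells.
- **Tmin**: Tmax minus a 12 °C base diurnal range, compressed by
  $\gamma = 6$ °C during humid episodes, plus 1 °C noise, clipped to
  Tmin ≤ Tmax. Warm anomalies on dry days therefore produce
  daytime-accentuated events; warm anomalies during humid episodes produce
  nighttime-accentuated ones. $\gamma \ge$ diurnal range is rejected.
- **Counts**: each stratum draws a baseline log-rate from
  $N(\log \lambda_0, \tau^2)$ ($\lambda_0 = 2$, $\tau = 0.2$); the day
  mean is $\exp(\text{baseline} + \beta_1 DHWI + \beta_2 NHWI)$ (plus
  optional lag terms); counts are Poisson or negative binomial with size
  $k$. True per-day expected excess counts,
  $\mu\,(1 - e^{-\beta \cdot HWI})$ per type, are recorded as a
  ground-truth sidecar for the attribution oracle.

Thresholds for synthetic runs are computed from a generated 30-season
reference period, mirroring a real climatology rather than using fixed
constants. Random streams are separated by purpose (climate anomalies,
humidity, baselines, counts), so changing one parameter group leaves the
other streams identical — useful for controlled comparisons.

Named scenarios freeze the study conditions: `paper_anchored` uses 50
locations and 3 analysis seasons with $\beta_1 = \log 1.0034$ and
$\beta_2 = \log 1.0123$ — per-degree effects of 0.34% and 1.23%, anchored
to published case-crossover estimates for mental-disorder acute care —
and baseline mean count 2; `null` sets both effects to zero (20 locations,
2 seasons) for size checks; `overdispersed` switches to negative-binomial
counts with $k = 1$; `lagged` places the nighttime effect entirely at lag
2; `nighttime_dominant` raises $\gamma$ to 8 °C with more frequent humid
episodes. Sizes were chosen once as small-state analogues that give
informative but fast simulations; the test suite runs 400 null replicates
for the type-I error check and 100 replicates each of the recovery
scenarios.

What the generator does **not** emulate: spatial correlation between
locations, long-term warming trends within the analysis window,
day-of-week structure in counts, humidity-dependent health effects, and
real geographic heterogeneity of thresholds. Passing tests therefore
demonstrate the statistical machinery — unbiased recovery of the
generating coefficients, correct test size and interval coverage,
consistent attribution — under the model's own assumptions, not the
validity of those assumptions for any particular real dataset.

## Numerical choices and edge cases

- Quantiles: type 7 everywhere (thresholds, spline knots, Monte Carlo
  percentiles), for determinism and consistency.
- Newton convergence: relative conditional log-likelihood change
  $< 10^{-10}$ or 100 iterations, with step halving; failure to converge
  is an error reporting the gradient norm, never a silent result.
- Panels with no residual degrees of freedom return Poisson (unscaled)
  standard errors and an undefined dispersion, and `estimate_dispersion()`
  errors rather than inventing one.
- Overlapping events, duplicate location-days, Tmin > Tmax, negative
  counts, unknown subgroup levels and records outside exposure coverage
  all fail loudly with the offending identifiers.
- All I/O is header-validated CSV with ISO dates; numeric round trips are
  exact to double precision.

## Limitations

The conditional estimator assumes counts are independent across days given
the stratum intercepts; with strong within-stratum serial correlation the
quasi-Poisson dispersion only partially compensates. Attribution treats
the fitted log-linear model as causal and the no-heatwave counterfactual
as well-defined. The two heatwave types' attributable numbers are computed
from separate AF formulas and added; on days where both indices are
positive this slightly double-counts at large effect sizes (negligible at
the percent-scale effects considered here).
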