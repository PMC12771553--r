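# nightheat

Daytime and nighttime heatwaves are different exposures: hot days strain
people while they are active; hot, typically humid nights deny the
overnight recovery that limits cumulative heat strain. `nightheat` is an R
package for epidemiologists who want to separate the two. From daily
maximum and minimum temperatures it builds *daytime* and *nighttime
heatwave indices* (HWIs), classifies heatwave events as daytime- or
nighttime-accentuated, estimates the association of each index with daily
health-event counts in a time-stratified case-crossover design, tests
whether the two effects differ, and converts coefficients into annual
heatwave-attributable burden. A synthetic-data generator with known ground
truth stands in for confidential health data and backs the simulation
tests.

## The model

Per location, thresholds are the 95th percentiles of warm-season
(May–October) daily Tmax and Tmin over a 30-year reference climatology. A
heatwave is ≥ 2 consecutive days with Tmax or Tmin strictly above
threshold; the event is daytime-accentuated when
$\sum \max(0, T_{max}-thr_{max}) > \sum \max(0, T_{min}-thr_{min})$ over
the event, nighttime-accentuated otherwise. On event days the daily
indices are those excesses; elsewhere both are 0.

Counts $Y$ follow a conditional quasi-Poisson case-crossover model,

$$\log E(Y) = \alpha + \beta_1\,\mathrm{DHWI} + \beta_2\,\mathrm{NHWI} + \beta_3\,\mathrm{Stratum},$$

with strata defined by location × year × month × weekday. Stratum
intercepts are eliminated by conditioning on stratum totals (numerically
identical to a stratum-dummy Poisson fit); standard errors scale by the
Pearson dispersion. Effects are reported as
$(e^{\beta}-1)\times 100$ percent change per 1 °C. Two estimates are
compared via $d = E_1-E_2$, $SE_d=\sqrt{SE_1^2+SE_2^2}$ (Bonferroni
adjustment for subgroup families), and burden is
$AF = 1-e^{-\beta\,\mathrm{HWI}}$, $AN = AF \times$ count, summed to
annual totals per heatwave type with Monte Carlo intervals.

Binary-event, natural-spline, single-lag (0–6) and humidity-adjusted
variants of the model are included. See `vignettes/methods.Rmd` for the
full methodological account.

## Worked example

Comparing two published percent-change estimates (nighttime 1.23%, 95% CI
1.00–1.46; daytime 0.34%, 95% CI 0.20–0.49):

```r
library(nightheat)
compare_estimates(1.23, 0.34, ci1 = c(1.00, 1.46), ci2 = c(0.20, 0.49),
                  labels = c("nighttime", "daytime"))
#>     label_1 label_2    d  se_d ci_low ci_high    z p_value
#> 1 nighttime daytime 0.89 0.139  0.618    1.16 6.42 1.4e-10
```

The nighttime effect is 0.89 percentage points larger (95% CI 0.62–1.16),
a difference that is clearly significant.

A full synthetic analysis — 50 locations, 3 seasons, true per-degree
effects 0.34% (daytime) and 1.23% (nighttime), baseline mean count 2:

```r
sim <- simulate_scenario(make_scenario("paper_anchored", seed = 7))
res <- run_pipeline(sim$climate, sim$health, seed = 7, n_draws = 500)
res$fit
#> Conditional quasi-Poisson case-crossover fit (linear_hwi)
#>   informative strata: 1596;  rows used: 7053;  dispersion phi = 0.9832
#>  term estimate std_error percent_change  ci_low ci_high p_value
#>  dhwi 0.005493  0.014310         0.5509 -2.2302   3.411  0.7011
#>  nhwi 0.009948  0.008872         0.9997 -0.7413   2.771  0.2622

dplyr::filter(res$attribution, component == "total")
#>   year component    an ci_low ci_high share_nighttime
#> 1 2017     total 29.02 -13.00   66.06          0.8062
#> 2 2018     total 25.85 -12.18   58.71          0.7923
#> 3 2019     total 22.44 -13.52   52.90          0.7128
```

Estimates (0.55%/°C daytime, 1.00%/°C nighttime) recover the generating
effects within their sampling error for a single replicate; the dispersion
near 1 reflects the Poisson generator. Attribution assigns 71–81% of the
annual heatwave-attributable counts to nighttime heatwaves, the dominant
component under these effect sizes. `autoplot(res$fit)`,
`plot_attribution(res$attribution)` and `plot_exposure_response()`
visualize estimates, burden and spline curves.

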