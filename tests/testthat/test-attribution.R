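test_that("attributable fraction follows the counterfactual formula", {
  expect_equal(attributable_fraction_day(log(1.0123), 0), 0)
  expect_equal(attributable_fraction_day(log(1.0123), 2),
               1 - 1.0123^(-2), tolerance = 1e-12)
  expect_equal(attributable_fraction_day(log(1.0123), 2), 0.02415,
               tolerance = 1e-3)
  # protective coefficient gives a negative fraction
  expect_lt(attributable_fraction_day(-0.05, 3), 0)
  # strictly increasing in exposure for positive beta, bounded above by 1
  af <- attributable_fraction_day(0.2, seq(0, 20, by = 0.5))
  expect_true(all(diff(af) > 0))
  expect_true(all(af < 1))
  expect_error(attributable_fraction_day(0.1, -1), "non-negative")
})

test_that("attributable numbers scale counts and add up across days", {
  panel <- tibble::tibble(
    location_id = "Z", date = as.Date("2019-07-02"), year = 2019,
    count = 100L, dhwi = 0, nhwi = 2, dhw_flag = 0L, nhw_flag = 1L
  )
  an <- attributable_number(panel, c(dhwi = log(1.0034), nhwi = log(1.0123)))
  expect_equal(an$annual$an_nighttime, 100 * (1 - 1.0123^(-2)),
               tolerance = 1e-12)
  expect_equal(an$annual$an_nighttime, 2.415, tolerance = 1e-3)
  expect_equal(an$annual$an_daytime, 0)

  # all-zero exposure: zero attribution everywhere
  z <- dplyr::mutate(panel, dhwi = 0, nhwi = 0)
  anz <- attributable_number(z, c(dhwi = 0.1, nhwi = 0.1))
  expect_equal(anz$annual$an_total, 0)

  # additivity: daily sums equal annual totals, components sum to total
  sim <- simulate_scenario(scenario_config(seed = 9, n_locations = 8,
                                           analysis_years = 2018:2019))
  p <- assemble_panel(sim$health, sim$exposure)
  fit <- fit_conditional_poisson(p)
  res <- attributable_number(p, fit)
  daily_sum <- res$daily %>%
    dplyr::group_by(year) %>%
    dplyr::summarise(d = sum(an_daytime), n = sum(an_nighttime))
  expect_equal(daily_sum$d, res$annual$an_daytime)
  expect_equal(daily_sum$n, res$annual$an_nighttime)
  expect_equal(res$annual$an_total,
               res$annual$an_daytime + res$annual$an_nighttime)
})

test_that("plugging generator truth into attribution recovers true excess", {
  # observed-count AN with true betas estimates the generator's recorded
  # expected excess; compare pooled over years against Poisson error
  tot_an <- 0; tot_truth <- 0; var_bound <- 0
  for (s in 1:5) {
    sim <- simulate_scenario(make_scenario("paper_anchored", seed = 100 + s))
    p <- assemble_panel(sim$health, sim$exposure)
    truth <- sim$truth
    an <- attributable_number(
      p, c(dhwi = attr(truth, "beta1"), nhwi = attr(truth, "beta2"))
    )
    tot_an <- tot_an + sum(an$annual$an_total)
    tot_truth <- tot_truth +
      sum(truth$true_excess_daytime + truth$true_excess_nighttime)
    # AN = AF * y with y Poisson(mu): Var(AN) = sum (AF_d + AF_n)^2 mu
    daily <- attr(truth, "daily")
    afd <- 1 - exp(-attr(truth, "beta1") * p$dhwi)
    afn <- 1 - exp(-attr(truth, "beta2") * p$nhwi)
    var_bound <- var_bound + sum((afd + afn)^2 * daily$mu)
  }
  expect_lt(abs(tot_an - tot_truth), 4 * sqrt(var_bound))
})

test_that("Monte Carlo attribution intervals are seeded and scale with SEs", {
  sim <- simulate_scenario(scenario_config(seed = 14, n_locations = 10,
                                           analysis_years = 2018:2019))
  p <- assemble_panel(sim$health, sim$exposure)
  fit <- fit_conditional_poisson(p)

  u1 <- attribution_uncertainty(p, fit, n_draws = 300, seed = 5)
  u2 <- attribution_uncertainty(p, fit, n_draws = 300, seed = 5)
  expect_identical(u1, u2)  # bit-reproducible
  u3 <- attribution_uncertainty(p, fit, n_draws = 300, seed = 6)
  expect_false(identical(u1$ci_low, u3$ci_low))

  # near-degenerate covariance collapses the interval onto the point
  fit0 <- fit
  fit0$vcov <- fit$vcov * 1e-18
  u0 <- attribution_uncertainty(p, fit0, n_draws = 300, seed = 5)
  expect_equal(u0$ci_low, u0$an, tolerance = 1e-3)
  expect_equal(u0$ci_high, u0$an, tolerance = 1e-3)

  # quartering the covariance roughly halves the interval width
  fit4 <- fit
  fit4$vcov <- fit$vcov / 4
  u4 <- attribution_uncertainty(p, fit4, n_draws = 1000, seed = 5)
  uf <- attribution_uncertainty(p, fit, n_draws = 1000, seed = 5)
  w_full <- uf$ci_high - uf$ci_low
  w_quarter <- u4$ci_high - u4$ci_low
  ratio <- w_quarter[w_full > 1e-8] / w_full[w_full > 1e-8]
  expect_true(all(abs(ratio - 0.5) < 0.15))
})
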