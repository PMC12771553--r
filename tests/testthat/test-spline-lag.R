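test_that("spline curve is anchored at zero and tracks a linear truth", {
  sim <- simulate_scenario(make_scenario("paper_anchored", seed = 3))
  panel <- assemble_panel(sim$health, sim$exposure)
  fit <- fit_spline_model(panel)
  curves <- fit$extra$curves

  at0 <- dplyr::filter(curves, hwi == 0)
  expect_equal(at0$log_rr, c(0, 0))
  expect_equal(at0$se, c(0, 0))

  # knots at P10/P50 of heatwave-day (positive) values
  pos <- panel$nhwi[panel$nhwi > 0]
  expect_equal(fit$extra$knots$nhwi,
               unname(quantile(pos, c(0.10, 0.50), type = 7)))

  # generated truth is linear: the spline curve should contain the true
  # line within its 95% band over the bulk of the observed range
  truth_b2 <- log(1.0123)
  nhw <- dplyr::filter(curves, exposure == "nhwi",
                       hwi <= quantile(panel$nhwi[panel$nhwi > 0], 0.9))
  cover <- mean(nhw$ci_low <= truth_b2 * nhw$hwi &
                  truth_b2 * nhw$hwi <= nhw$ci_high)
  expect_gte(cover, 0.8)
})

test_that("spline knot handling rejects degenerate configurations", {
  panel <- tibble::tibble(
    stratum = rep(c("a", "b"), each = 4),
    count = c(1L, 2L, 1L, 3L, 2L, 1L, 2L, 1L),
    dhwi = c(0, 1, 1, 1, 0, 1, 1, 1),  # only one distinct positive value
    nhwi = c(0, 0.5, 1, 2, 0, 0.7, 1.2, 2.5)
  )
  expect_error(fit_spline_model(panel), "dhwi")
  expect_error(fit_spline_model(panel, knot_percentiles = c(0.5, 0.2)),
               "increasing")
})

test_that("lag 0 reproduces the main fit and lags must lie in 0..6", {
  sim <- simulate_scenario(scenario_config(seed = 5, n_locations = 10,
                                           analysis_years = 2018:2019))
  panel <- assemble_panel(sim$health, sim$exposure)
  main <- fit_conditional_poisson(panel)
  lag0 <- fit_lag_model(panel, 0)
  expect_equal(lag0$beta, main$beta, tolerance = 1e-12)
  expect_error(fit_lag_model(panel, 7), "between 0 and 6")
  expect_error(fit_lag_model(panel, -1), "between 0 and 6")

  # a lag-1 fit uses exposure from the previous day: shifting exposure by
  # one day and refitting at lag 0 gives the same coefficients
  lag1 <- fit_lag_model(panel, 1)
  expect_false(isTRUE(all.equal(lag1$beta, main$beta)))
  expect_lt(lag1$n_rows_used, main$n_rows_used + 1)
})

test_that("lagged generator effect is recovered at the generating lag", {
  # nighttime effect only at lag 2; the estimated nighttime coefficient
  # across single-lag models should peak at lag 2 (averaged over 3 seeds)
  betas <- matrix(0, 3, 4)
  for (s in 1:3) {
    sim <- simulate_scenario(make_scenario("lagged", seed = s))
    panel <- assemble_panel(sim$health, sim$exposure)
    for (k in 0:3) {
      f <- fit_lag_model(panel, k)
      betas[s, k + 1] <- f$beta[["nhwi"]]
    }
  }
  mean_beta <- colMeans(betas)
  expect_equal(which.max(mean_beta), 3L)  # lag 2
  expect_gt(mean_beta[3], 0.5 * log(1.08))
})

test_that("binary event model estimates per-event-day effects", {
  sim <- simulate_scenario(make_scenario("paper_anchored", seed = 11))
  panel <- assemble_panel(sim$health, sim$exposure)
  fit <- fit_binary_model(panel)
  expect_setequal(fit$terms, c("dhw_flag", "nhw_flag"))

  # the generator's effect is per degree C; the implied per-event-day
  # effect must exceed the per-degree effect when mean event-day intensity
  # exceeds 1 degree C
  mean_nhwi <- mean(panel$nhwi[panel$nhw_flag == 1])
  expect_gt(mean_nhwi, 1)
  td <- tidy(fit)
  b_night <- td$estimate[td$term == "nhw_flag"]
  se_night <- td$std_error[td$term == "nhw_flag"]
  # within 3 SE of the aggregated truth beta2 * mean intensity
  expect_lt(abs(b_night - log(1.0123) * mean_nhwi), 3 * se_night)

  # no heatwave days at all: unidentifiable
  flat <- dplyr::mutate(panel, dhw_flag = 0L, nhw_flag = 0L)
  expect_error(fit_binary_model(flat), "unidentifiable")
})
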