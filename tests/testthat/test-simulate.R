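test_that("generation is bit-reproducible and seed-sensitive", {
  cfg <- scenario_config(seed = 4, n_locations = 3, analysis_years = 2018,
                         reference_years = 2008:2012)
  a <- simulate_scenario(cfg)
  b <- simulate_scenario(cfg)
  expect_identical(a$climate, b$climate)
  expect_identical(a$health, b$health)
  cfg2 <- cfg; cfg2$seed <- 5L
  c2 <- simulate_scenario(cfg2)
  expect_false(identical(a$climate$tmax, c2$climate$tmax))
})

test_that("random streams are separated by purpose", {
  cfg <- scenario_config(seed = 4, n_locations = 3, analysis_years = 2018,
                         reference_years = 2008:2012)
  base <- gen_temperature(cfg)
  # changing only the humidity process leaves the anomaly stream intact:
  # dry-day tmax values are unchanged
  cfg_h <- cfg
  cfg_h$climate$humid_freq <- 0.5
  alt <- gen_temperature(cfg_h)
  expect_identical(base$tmax, alt$tmax)
  expect_false(identical(base$tmin, alt$tmin))
})

test_that("degenerate climate parameters produce no heatwaves", {
  cfg <- scenario_config(seed = 6, n_locations = 2, analysis_years = 2018,
                         reference_years = 2008:2012,
                         climate = list(sigma = 0, gamma = 0, mean_amp = 0,
                                        tmin_noise_sd = 0))
  sim <- simulate_scenario(cfg)
  expect_equal(nrow(sim$events), 0)
  expect_true(all(sim$exposure$dhwi == 0 & sim$exposure$nhwi == 0))
})

test_that("gamma at or above the diurnal range is rejected", {
  cfg <- scenario_config(seed = 1, climate = list(gamma = 12,
                                                  diurnal_range = 12))
  expect_error(gen_temperature(cfg), "diurnal_range")
})

test_that("both event types occur and gamma tilts the balance nightward", {
  ratio_at <- function(gamma, seed) {
    cfg <- scenario_config(seed = seed, n_locations = 6,
                           analysis_years = 2017:2019,
                           reference_years = 1997:2006,
                           climate = list(gamma = gamma))
    sim <- simulate_scenario(cfg)
    n_day <- sum(sim$events$duration[sim$events$event_type ==
                                       "daytime_accentuated"])
    n_night <- sum(sim$events$duration[sim$events$event_type ==
                                         "nighttime_accentuated"])
    c(day = n_day, night = n_night)
  }
  lo <- rowSums(sapply(1:4, function(s) ratio_at(2, s)))
  hi <- rowSums(sapply(1:4, function(s) ratio_at(8, s)))
  # default-like configs produce both types
  expect_gt(lo[["day"]], 0)
  expect_gt(hi[["night"]], 0)
  # stronger humid compression raises the nighttime:daytime day ratio
  expect_gt(hi[["night"]] / max(hi[["day"]], 1),
            lo[["night"]] / max(lo[["day"]], 1))
})

test_that("null scenario counts are uncorrelated with exposure", {
  cors <- sapply(1:5, function(s) {
    sim <- simulate_scenario(make_scenario("null", seed = s))
    p <- assemble_panel(sim$health, sim$exposure)
    hw <- p$dhwi + p$nhwi
    cor(p$count, hw)
  })
  # each panel's correlation has Monte Carlo SD ~ 1/sqrt(n) ~ 0.012
  expect_lt(abs(mean(cors)), 3 * 0.012 / sqrt(length(cors)))
})

test_that("Poisson mode is equidispersed and negative binomial is not", {
  cfg <- scenario_config(seed = 8, n_locations = 10, analysis_years = 2018,
                         reference_years = 2003:2012)
  sim <- simulate_scenario(cfg)
  p <- assemble_panel(sim$health, sim$exposure)
  fit <- fit_conditional_poisson(p)
  expect_equal(fit$dispersion, 1, tolerance = 0.12)

  cfg_nb <- cfg
  cfg_nb$health$dispersion_k <- 1
  sim_nb <- simulate_scenario(cfg_nb)
  p_nb <- assemble_panel(sim_nb$health, sim_nb$exposure)
  fit_nb <- fit_conditional_poisson(p_nb)
  expect_gt(fit_nb$dispersion, 1.5)
})

test_that("subgroup splitting conserves totals and proportions", {
  cfg <- scenario_config(
    seed = 12, n_locations = 4, analysis_years = 2018,
    reference_years = 2008:2012,
    health = list(lambda0 = 5,
                  subgroups = list(sex = c(male = 0.4, female = 0.6)))
  )
  sim <- simulate_scenario(cfg)
  expect_setequal(unique(sim$health$sex), c("male", "female"))
  tot <- sum(sim$health$count)
  f <- sum(filter_subgroup(sim$health, sex = "female")$count)
  m <- sum(filter_subgroup(sim$health, sex = "male")$count)
  expect_equal(f + m, tot)
  expect_equal(f / tot, 0.6, tolerance = 0.05)
})

test_that("scenario registry returns the documented configurations", {
  expect_equal(make_scenario("null")$health$beta1, 0)
  expect_equal(make_scenario("null")$health$beta2, 0)
  pa <- make_scenario("paper_anchored")
  expect_equal(exp(pa$health$beta1), 1.0034)
  expect_equal(exp(pa$health$beta2), 1.0123)
  expect_equal(make_scenario("overdispersed")$health$dispersion_k, 1)
  expect_error(make_scenario("unknown"), "arg")
})
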