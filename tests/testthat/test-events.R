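test_that("worked 6-day example: one daytime event, isolated day excluded", {
  clim <- example_climate_6day()
  thr <- example_thresholds()
  ev <- detect_heatwave_events(clim, thr)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$start_date, as.Date("2019-07-02"))
  expect_equal(ev$end_date, as.Date("2019-07-03"))
  expect_equal(ev$cum_excess_tmax, 3)
  expect_equal(ev$cum_excess_tmin, 1)
  expect_equal(ev$event_type, "daytime_accentuated")

  # 3-day minimum duration: the 2-day run no longer qualifies
  expect_equal(nrow(detect_heatwave_events(clim, thr, min_duration = 3)), 0)

  # all days below both thresholds
  cold <- dplyr::mutate(clim, tmax = 20, tmin = 10)
  expect_equal(nrow(detect_heatwave_events(cold, thr)), 0)
})

test_that("event sets equal brute-force enumeration on short series", {
  for (seed in 1:12) {
    drop <- if (seed %% 3 == 0) 3 else 0  # some series have missing days
    clim <- random_climate(seed, n_days = 31, drop_days = drop)
    thr <- tibble::tibble(location_id = "L1",
                          tmax_threshold = 31, tmin_threshold = 19)
    for (md in 2:3) {
      got <- detect_heatwave_events(clim, thr, min_duration = md)
      want <- brute_force_events(clim$date, clim$tmax, clim$tmin,
                                 31, 19, min_duration = md)
      expect_equal(nrow(got), nrow(want), info = paste("seed", seed, "md", md))
      if (nrow(want) > 0) {
        expect_equal(got$start_date, want$start_date)
        expect_equal(got$end_date, want$end_date)
        expect_equal(got$event_type, want$event_type)
        expect_equal(got$cum_excess_tmax, want$cum_excess_tmax)
        expect_equal(got$cum_excess_tmin, want$cum_excess_tmin)
      }
    }
  }
})

test_that("runs never span date gaps or season boundaries", {
  # hot streak interrupted by a missing day
  clim <- random_climate(1, n_days = 6)
  clim$tmax <- 35
  clim$tmin <- 22
  clim <- clim[-3, ]
  thr <- tibble::tibble(location_id = "L1",
                        tmax_threshold = 31, tmin_threshold = 19)
  ev <- detect_heatwave_events(clim, thr)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$duration, c(2, 3))

  # October -> May of the next year never merges even with contiguous rows
  d <- c(seq(as.Date("2018-10-29"), as.Date("2018-10-31"), by = "day"),
         seq(as.Date("2019-05-01"), as.Date("2019-05-03"), by = "day"))
  clim2 <- tibble::tibble(location_id = "L1", date = d, tmax = 35, tmin = 22)
  ev2 <- detect_heatwave_events(clim2, thr)
  expect_equal(nrow(ev2), 2)
  expect_true(all(ev2$duration == 3))
})

test_that("raising the percentile level never adds event days", {
  for (seed in 1:6) {
    cfg <- scenario_config(seed = seed, n_locations = 3,
                           analysis_years = 2018, reference_years = 1998:2007)
    clim <- gen_temperature(cfg)
    analysis <- dplyr::filter(clim, lubridate::year(date) == 2018)
    days_at <- function(p) {
      thr <- compute_thresholds(clim, percentile_level = p,
                                reference_period = c(1998, 2007))
      ev <- detect_heatwave_events(analysis, thr)
      if (nrow(ev) == 0) 0 else sum(ev$duration)
    }
    expect_lte(days_at(0.95), days_at(0.90))
  }
})

test_that("classification is exhaustive, exclusive, and flips under day/night swap", {
  clim <- random_climate(4, n_days = 31)
  clim$tmax <- clim$tmax + 3  # ensure some events
  thr <- tibble::tibble(location_id = "L1",
                        tmax_threshold = 31, tmin_threshold = 19)
  ev <- detect_heatwave_events(clim, thr)
  expect_gt(nrow(ev), 0)
  expect_true(all(ev$event_type %in%
                    c("daytime_accentuated", "nighttime_accentuated")))

  # swapping tmax/tmin together with their thresholds swaps the labels
  swapped <- dplyr::mutate(clim, tmp = tmax, tmax = tmin + 100,
                           tmin = tmp - 100)
  swapped$tmp <- NULL
  thr_sw <- tibble::tibble(location_id = "L1",
                           tmax_threshold = 19 + 100,
                           tmin_threshold = 31 - 100)
  ev_sw <- detect_heatwave_events(swapped, thr_sw)
  expect_equal(nrow(ev_sw), nrow(ev))
  # ties (none expected here) aside, labels must be exchanged
  no_tie <- ev$cum_excess_tmax != ev$cum_excess_tmin
  expect_true(all(ev$event_type[no_tie] != ev_sw$event_type[no_tie]))
})

test_that("exact classification ties go to nighttime", {
  d <- seq(as.Date("2019-07-01"), by = "day", length.out = 2)
  clim <- tibble::tibble(location_id = "A", date = d,
                         tmax = c(32, 32), tmin = c(17, 17))
  ev <- detect_heatwave_events(clim, example_thresholds())
  expect_equal(ev$cum_excess_tmax, ev$cum_excess_tmin)
  expect_equal(ev$event_type, "nighttime_accentuated")
})

test_that("missing thresholds for a present location fail by name", {
  clim <- example_climate_6day()
  thr <- tibble::tibble(location_id = "B",
                        tmax_threshold = 30, tmin_threshold = 15)
  expect_error(detect_heatwave_events(clim, thr), "A")
})
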