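# Independent oracles and small fixture builders used across the suite.

# Exhaustive run enumeration: checks every (start, end) day pair of a single
# location's series and keeps maximal consecutive-date runs in which every
# day exceeds either threshold. Deliberately brute force (O(n^2)); the
# reference for detect_heatwave_events on short series.
brute_force_events <- function(dates, tmax, tmin, thr_max, thr_min,
                               min_duration = 2) {
  n <- length(dates)
  exceed <- tmax > thr_max | tmin > thr_min
  out <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (!all(exceed[i:j])) next
      if (j > i && any(diff(dates[i:j]) != 1)) next
      # maximality: no qualifying extension on either side
      left_ok <- i == 1 || !exceed[i - 1] || dates[i] - dates[i - 1] != 1
      right_ok <- j == n || !exceed[j + 1] || dates[j + 1] - dates[j] != 1
      if (!left_ok || !right_ok) next
      if (j - i + 1 < min_duration) next
      cx <- sum(pmax(0, tmax[i:j] - thr_max))
      cn <- sum(pmax(0, tmin[i:j] - thr_min))
      out[[length(out) + 1]] <- data.frame(
        start_date = dates[i], end_date = dates[j],
        duration = j - i + 1,
        event_type = if (cx > cn) "daytime_accentuated" else "nighttime_accentuated",
        cum_excess_tmax = cx, cum_excess_tmin = cn
      )
    }
  }
  if (length(out) == 0) {
    return(data.frame(start_date = as.Date(character()),
                      end_date = as.Date(character()),
                      duration = integer(), event_type = character(),
                      cum_excess_tmax = numeric(),
                      cum_excess_tmin = numeric()))
  }
  do.call(rbind, out)
}

# Stratum-dummy Poisson fit: the independent equivalence oracle for the
# conditional estimator.
dummy_poisson_fit <- function(panel, terms = c("dhwi", "nhwi")) {
  f <- stats::as.formula(paste("count ~", paste(terms, collapse = " + "),
                               "+ factor(stratum)"))
  stats::glm(f, family = stats::poisson(), data = panel)
}

# Small random case-crossover panel with known coefficients.
random_panel <- function(seed, n_strata = 25, beta = c(dhwi = 0.1, nhwi = 0.2),
                         lambda0 = 3) {
  set.seed(seed)
  rows <- lapply(seq_len(n_strata), function(s) {
    k <- sample(4:5, 1)
    data.frame(
      stratum = sprintf("s%02d", s),
      dhwi = round(stats::rexp(k), 2) * stats::rbinom(k, 1, 0.4),
      nhwi = round(stats::rexp(k), 2) * stats::rbinom(k, 1, 0.4)
    )
  })
  panel <- dplyr::as_tibble(do.call(rbind, rows))
  eta <- log(lambda0) + beta[["dhwi"]] * panel$dhwi + beta[["nhwi"]] * panel$nhwi
  panel$count <- stats::rpois(nrow(panel), exp(eta))
  panel
}

# Six-day single-location fixture matching the documented worked example:
# thresholds (30, 15); one 2-day daytime-accentuated event on days 2-3.
example_climate_6day <- function() {
  tibble::tibble(
    location_id = "A",
    date = seq(as.Date("2019-07-01"), by = "day", length.out = 6),
    tmax = c(29, 31, 32, 29, 31, 29),
    tmin = c(14, 14, 16, 14, 14, 14)
  )
}

example_thresholds <- function() {
  tibble::tibble(location_id = "A", tmax_threshold = 30, tmin_threshold = 15)
}

# Random short climate series for property tests (single location).
random_climate <- function(seed, n_days = 31, start = as.Date("2018-06-01"),
                           drop_days = 0) {
  set.seed(seed)
  dates <- seq(start, by = "day", length.out = n_days)
  if (drop_days > 0) dates <- sort(sample(dates, n_days - drop_days))
  tmax <- round(stats::rnorm(length(dates), 30, 3), 1)
  tmin <- tmax - round(stats::runif(length(dates), 8, 14), 1)
  tibble::tibble(location_id = "L1", date = dates, tmax = tmax, tmin = tmin)
}
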