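#' Generate synthetic daily temperature series
#'
#' Emulates the statistical structure the heatwave analysis assumes: daily
#' Tmax is a seasonal sinusoid plus an AR(1) anomaly; a two-state Markov
#' chain produces persistent humid episodes that compress the diurnal
#' range, so warm anomalies co-occurring with humid episodes yield
#' nighttime-accentuated heatwaves while dry warm anomalies yield
#' daytime-accentuated ones. Locations and seasons are independent; the
#' generator is deterministic given the config seed, and the climate and
#' humidity random streams are separated so changing one leaves the other
#' identical.
#'
#' @param config A scenario configuration from [make_scenario()] or
#'   [scenario_config()].
#' @return A tibble of daily records (`location_id`, `date`, `tmax`,
#'   `tmin`, and `rh` when `config$climate$emit_rh` is `TRUE`) covering the
#'   warm seasons of both the reference and the analysis years.
#' @export
gen_temperature <- function(config) {
  cl <- config$climate
  if (cl$gamma >= cl$diurnal_range) {
    abort("`gamma` must be below `diurnal_range` (would force tmin > tmax).")
  }
  years <- c(config$reference_years, config$analysis_years)
  months <- config$season_months

  # one column per location-season; AR(1) restarts each season
  season_dates <- lapply(years, function(yr) {
    d <- seq(as.Date(sprintf("%d-01-01", yr)),
             as.Date(sprintf("%d-12-31", yr)), by = "day")
    d[date_month(d) %in% months]
  })
  n_days <- lengths(season_dates)
  stopifnot(length(unique(n_days)) <= 2)  # leap years only
  n_loc <- config$n_locations
  loc_ids <- sprintf("L%03d", seq_len(n_loc))

  withr_seed <- function(s, code) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(s)
    code()
  }

  nd_max <- max(n_days)
  n_series <- length(years) * n_loc
  innov_sd <- cl$sigma * sqrt(1 - cl$rho^2)

  anom <- withr_seed(sub_seed(config$seed, "climate"), function() {
    a <- matrix(0, nd_max, n_series)
    a[1, ] <- rnorm(n_series, sd = cl$sigma)  # stationary start
    e <- matrix(rnorm((nd_max - 1) * n_series, sd = innov_sd),
                nd_max - 1, n_series)
    for (t in 2:nd_max) a[t, ] <- cl$rho * a[t - 1, ] + e[t - 1, ]
    a
  })
  tmin_noise <- withr_seed(sub_seed(config$seed, "climate") + 1L, function() {
    matrix(rnorm(nd_max * n_series, sd = cl$tmin_noise_sd), nd_max, n_series)
  })

  # persistent humid episodes: 2-state Markov chain per series
  p_hh <- cl$humid_persistence
  p_dh <- cl$humid_freq * (1 - p_hh) / (1 - cl$humid_freq)
  humid <- withr_seed(sub_seed(config$seed, "humidity"), function() {
    u <- matrix(runif(nd_max * n_series), nd_max, n_series)
    h <- matrix(FALSE, nd_max, n_series)
    h[1, ] <- u[1, ] < cl$humid_freq
    for (t in 2:nd_max) {
      h[t, ] <- u[t, ] < ifelse(h[t - 1, ], p_hh, p_dh)
    }
    h
  })
  rh_noise <- withr_seed(sub_seed(config$seed, "humidity") + 1L, function() {
    matrix(rnorm(nd_max * n_series, sd = 5), nd_max, n_series)
  })

  blocks <- vector("list", length(years))
  for (i in seq_along(years)) {
    dts <- season_dates[[i]]
    nd <- length(dts)
    doy <- lubridate::yday(dts)
    seasonal <- cl$mean_level + cl$mean_amp * cos(2 * pi * (doy - 196) / 365)
    cols <- (i - 1) * n_loc + seq_len(n_loc)
    tmax <- seasonal + anom[seq_len(nd), cols, drop = FALSE]
    hm <- humid[seq_len(nd), cols, drop = FALSE]
    tmin <- tmax - (cl$diurnal_range - cl$gamma * hm) +
      tmin_noise[seq_len(nd), cols, drop = FALSE]
    tmin <- pmin(tmin, tmax)
    blk <- tibble(
      location_id = rep(loc_ids, each = nd),
      date = rep(dts, times = n_loc),
      tmax = as.vector(tmax),
      tmin = as.vector(tmin)
    )
    if (isTRUE(cl$emit_rh)) {
      rh <- 45 + 35 * hm + rh_noise[seq_len(nd), cols, drop = FALSE]
      blk$rh <- pmin(100, pmax(5, as.vector(rh)))
    }
    blocks[[i]] <- blk
  }
  bind_rows(blocks) %>% arrange(.data$location_id, .data$date)
}

#' Generate synthetic daily health-event counts
#'
#' The data-generating inverse of the conditional quasi-Poisson model: each
#' case-crossover stratum receives a baseline log-rate drawn from
#' \eqn{N(\log \lambda_0, \tau^2)}; the day mean is
#' \eqn{\mu = \exp(\mathrm{baseline} + \beta_1 \mathrm{DHWI} +
#' \beta_2 \mathrm{NHWI})} (plus any configured lag terms); counts are
#' Poisson, or negative binomial with dispersion parameter `k` when
#' `config$health$dispersion_k` is set. The true expected excess count per
#' day and heatwave type, \eqn{\mu (1 - e^{-\beta \cdot hwi})}, is recorded
#' in a ground-truth sidecar for attribution oracles.
#'
#' @param config Scenario configuration.
#' @param exposure Daily exposure tibble from [compute_daily_hwi()] on the
#'   generated climate (analysis years).
#' @return A list: `health` (tibble `location_id`, `date`, `cause`,
#'   `count`, plus any subgroup attribute columns) and `truth` (per-year
#'   true expected excess counts per heatwave type, plus the true
#'   coefficients as attributes).
#' @export
gen_counts <- function(config, exposure) {
  he <- config$health
  if (he$lambda0 <= 0) abort("`lambda0` must be positive.")
  if (he$tau < 0) abort("`tau` must be non-negative.")

  x <- exposure %>%
    filter(date_year(.data$date) %in% config$analysis_years) %>%
    arrange(.data$location_id, .data$date)
  strata <- build_strata(x$date, x$location_id)
  skey <- strata$stratum
  ukey <- unique(skey)

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))

  set.seed(sub_seed(config$seed, "baseline"))
  base_log <- rnorm(length(ukey), mean = log(he$lambda0), sd = he$tau)
  eta <- base_log[match(skey, ukey)]

  # exposure effects; lag_effects is a tibble-like list(lag, beta1, beta2)
  lags <- he$lag_effects %||% list(lag = 0L, beta1 = he$beta1,
                                   beta2 = he$beta2)
  for (i in seq_along(lags$lag)) {
    l <- lags$lag[i]
    if (l == 0) {
      eta <- eta + lags$beta1[i] * x$dhwi + lags$beta2[i] * x$nhwi
    } else {
      shifted <- x %>%
        select("location_id", "date", "dhwi", "nhwi") %>%
        mutate(date = .data$date + l) %>%
        rename(dhwi_l = "dhwi", nhwi_l = "nhwi")
      xl <- left_join(select(x, "location_id", "date"), shifted,
                      by = c("location_id", "date"))
      eta <- eta + lags$beta1[i] * tidyr::replace_na(xl$dhwi_l, 0) +
        lags$beta2[i] * tidyr::replace_na(xl$nhwi_l, 0)
    }
  }
  mu <- exp(eta)

  set.seed(sub_seed(config$seed, "counts"))
  counts <- if (is.null(he$dispersion_k)) {
    rpois(length(mu), mu)
  } else {
    rnbinom(length(mu), size = he$dispersion_k, mu = mu)
  }

  health <- tibble(
    location_id = x$location_id, date = x$date,
    cause = he$cause %||% "all", count = counts
  )

  # optional single-attribute subgroup split (thinning preserves Poisson)
  if (!is.null(he$subgroups)) {
    attr_name <- names(he$subgroups)[1]
    props <- he$subgroups[[1]]
    set.seed(sub_seed(config$seed, "counts") + 1L)
    split_mat <- t(vapply(counts, function(n) {
      as.vector(stats::rmultinom(1, n, props))
    }, numeric(length(props))))
    health <- purrr::map_dfr(seq_along(props), function(j) {
      h <- health
      h$count <- split_mat[, j]
      h[[attr_name]] <- names(props)[j]
      h
    }) %>% arrange(.data$location_id, .data$date)
  }

  truth_daily <- tibble(
    location_id = x$location_id, date = x$date,
    year = date_year(x$date),
    mu = mu,
    true_excess_daytime = mu * (1 - exp(-he$beta1 * x$dhwi)),
    true_excess_nighttime = mu * (1 - exp(-he$beta2 * x$nhwi))
  )
  truth <- truth_daily %>%
    group_by(.data$year) %>%
    summarise(
      true_excess_daytime = sum(.data$true_excess_daytime),
      true_excess_nighttime = sum(.data$true_excess_nighttime),
      .groups = "drop"
    )
  attr(truth, "beta1") <- he$beta1
  attr(truth, "beta2") <- he$beta2
  attr(truth, "daily") <- truth_daily

  list(health = health, truth = truth)
}

#' Run a full synthetic scenario
#'
#' Generates climate for the reference and analysis periods, computes
#' thresholds from the reference climatology, detects and classifies
#' heatwave events in the analysis years, derives daily HWIs, and draws
#' health counts with known true coefficients.
#'
#' @param config Scenario configuration from [make_scenario()] or
#'   [scenario_config()].
#' @return A list with `climate`, `thresholds`, `events`, `exposure`,
#'   `health`, `truth`, and the `config`.
#' @export
simulate_scenario <- function(config) {
  climate <- gen_temperature(config)
  thresholds <- compute_thresholds(
    climate,
    percentile_level = config$percentile_level,
    reference_period = range(config$reference_years),
    season_months = config$season_months
  )
  analysis <- climate %>%
    filter(date_year(.data$date) %in% config$analysis_years)
  events <- detect_heatwave_events(analysis, thresholds,
                                   min_duration = config$min_duration,
                                   season_months = config$season_months)
  exposure <- compute_daily_hwi(analysis, thresholds, events,
                                season_months = config$season_months)
  cnt <- gen_counts(config, exposure)
  list(climate = climate, thresholds = thresholds, events = events,
       exposure = exposure, health = cnt$health, truth = cnt$truth,
       config = config)
}
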