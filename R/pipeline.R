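#' Run the full heatwave impact analysis pipeline
#'
#' Orchestrates every stage for one cause: threshold computation, heatwave
#' detection and classification, daily HWIs, case-crossover panel assembly,
#' conditional quasi-Poisson fits (main linear model plus any requested lag
#' and binary forms), daytime-vs-nighttime heterogeneity, and attributable
#' burden with Monte Carlo intervals. Deterministic given inputs and seed.
#'
#' Defaults reproduce a conventional main analysis: 95th-percentile
#' thresholds, 2-day minimum duration, May--October season, linear HWI
#' exposure at lag 0. Sensitivity toggles: `percentile_level = 0.90`,
#' `min_duration = 3` or `4`, and `covariates = "rh"` for a same-day
#' relative-humidity adjustment.
#'
#' @param climate Daily climate tibble (reference + analysis periods), or a
#'   path readable by [read_climate()].
#' @param health Daily health-count tibble, or a path for [read_health()].
#' @param cause Cause label to analyse (`NULL` = all pooled).
#' @param analysis_years Years to analyse; default all years with health
#'   records.
#' @param reference_period Length-2 year range for thresholds; default all
#'   climate years before the first analysis year.
#' @param percentile_level,min_duration,season_months Heatwave definition
#'   (see [compute_thresholds()], [detect_heatwave_events()]).
#' @param covariates Extra linear covariates for the fit (e.g. `"rh"`).
#' @param lags Integer lags to fit as separate single-lag models
#'   (default `0`).
#' @param fit_binary Also fit the binary event-indicator model.
#' @param n_draws,seed Monte Carlo settings for attribution intervals.
#' @param out_dir Optional directory; when given, every stage's table is
#'   written there as CSV.
#'
#' @return A list of results: `thresholds`, `events`, `exposure`, `panel`,
#'   `fit`, `estimates` (percent changes), `comparison` (daytime vs
#'   nighttime heterogeneity), `lag_estimates`, `binary_estimates`,
#'   `attribution`, and a `log` tibble of stage diagnostics.
#' @export
run_pipeline <- function(climate, health, cause = NULL,
                         analysis_years = NULL,
                         reference_period = NULL,
                         percentile_level = 0.95,
                         min_duration = 2,
                         season_months = .default_season,
                         covariates = character(),
                         lags = 0L,
                         fit_binary = FALSE,
                         n_draws = 1000, seed = 1L,
                         out_dir = NULL) {
  if (is.character(climate)) climate <- read_climate(climate)
  if (is.character(health)) health <- read_health(health)

  analysis_years <- analysis_years %||%
    sort(unique(date_year(health$date)))
  reference_period <- reference_period %||%
    c(min(date_year(climate$date)), min(analysis_years) - 1)

  log <- list()
  note <- function(stage, ...) {
    log[[length(log) + 1]] <<- tibble(stage = stage,
                                      detail = paste0(...))
  }

  thresholds <- compute_thresholds(climate, percentile_level,
                                   reference_period, season_months)
  note("thresholds", nrow(thresholds), " locations, P",
       round(100 * percentile_level), ", reference ",
       reference_period[1], "-", reference_period[2])

  analysis_climate <- climate %>%
    filter(date_year(.data$date) %in% analysis_years)
  events <- detect_heatwave_events(analysis_climate, thresholds,
                                   min_duration, season_months)
  note("events", nrow(events), " events (",
       sum(events$event_type == "daytime_accentuated"), " daytime, ",
       sum(events$event_type == "nighttime_accentuated"), " nighttime)")

  exposure <- compute_daily_hwi(analysis_climate, thresholds, events,
                                season_months)
  note("exposure", nrow(exposure), " location-days, ",
       sum(exposure$dhwi > 0 | exposure$nhwi > 0), " heatwave days")

  panel <- assemble_panel(health, exposure, cause = cause)
  note("panel", nrow(panel), " rows, ", attr(panel, "dropped_days"),
       " dropped for missing exposure, total count ", sum(panel$count))

  fit <- fit_conditional_poisson(panel, covariates = covariates)
  est <- tidy(fit) %>% filter(.data$term %in% c("dhwi", "nhwi"))
  note("fit", "phi = ", format(fit$dispersion, digits = 4), ", ",
       fit$n_informative_strata, " informative strata, ",
       fit$iterations, " iterations")

  comparison <- compare_estimates(
    est$percent_change[est$term == "nhwi"],
    est$percent_change[est$term == "dhwi"],
    se1 = se_from_ci(est$ci_low[est$term == "nhwi"],
                     est$ci_high[est$term == "nhwi"]),
    se2 = se_from_ci(est$ci_low[est$term == "dhwi"],
                     est$ci_high[est$term == "dhwi"]),
    labels = c("nighttime", "daytime")
  )
  note("comparison", "d = ", format(comparison$d, digits = 3),
       ", p = ", format(comparison$p_value, digits = 3))

  lag_estimates <- purrr::map_dfr(setdiff(lags, 0L), function(k) {
    lf <- fit_lag_model(panel, k, covariates = covariates)
    tidy(lf) %>% filter(.data$term %in% c("dhwi", "nhwi")) %>%
      mutate(lag = k, .before = 1)
  })
  if (0L %in% lags) {
    lag_estimates <- bind_rows(mutate(est, lag = 0L, .before = 1),
                               lag_estimates)
  }

  binary_estimates <- NULL
  if (fit_binary) {
    bf <- fit_binary_model(panel, covariates = covariates)
    binary_estimates <- tidy(bf) %>%
      filter(.data$term %in% c("dhw_flag", "nhw_flag"))
  }

  attribution <- attribution_uncertainty(panel, fit, n_draws = n_draws,
                                         seed = seed)
  tot <- attribution %>% filter(.data$component == "total")
  note("attribution", "mean annual total AN = ",
       format(mean(tot$an), digits = 4), ", nighttime share = ",
       format(mean(tot$share_nighttime), digits = 3))

  res <- list(
    thresholds = thresholds, events = events, exposure = exposure,
    panel = panel, fit = fit, estimates = est, comparison = comparison,
    lag_estimates = lag_estimates, binary_estimates = binary_estimates,
    attribution = attribution, log = bind_rows(log)
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_table(as_tibble(thresholds), file.path(out_dir, "thresholds.csv"))
    write_table(events, file.path(out_dir, "events.csv"))
    write_table(exposure, file.path(out_dir, "exposure.csv"))
    write_table(panel, file.path(out_dir, "panel.csv"))
    write_table(est, file.path(out_dir, "estimates.csv"))
    write_table(comparison, file.path(out_dir, "comparison.csv"))
    write_table(lag_estimates, file.path(out_dir, "lag_estimates.csv"))
    if (!is.null(binary_estimates)) {
      write_table(binary_estimates, file.path(out_dir, "binary_estimates.csv"))
    }
    write_table(attribution, file.path(out_dir, "attribution.csv"))
    write_table(res$log, file.path(out_dir, "run_log.csv"))
  }
  res
}
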