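#' Detect and classify heatwave events
#'
#' A heatwave is a run of at least `min_duration` consecutive warm-season
#' days on which either daily Tmax or daily Tmin is strictly above its local
#' threshold. Each event is classified as *daytime-accentuated* when the
#' cumulative excess Tmax over the event exceeds the cumulative excess Tmin,
#' and *nighttime-accentuated* otherwise (exact ties, which have probability
#' zero for continuous temperatures, are assigned to nighttime).
#'
#' Runs never span a calendar-date gap, a missing day, or the boundary
#' between warm seasons of adjacent years: every season is processed
#' independently.
#'
#' @param climate Daily climate tibble (`location_id`, `date`, `tmax`,
#'   `tmin`), restricted to (or filterable to) the warm season.
#' @param thresholds Output of [compute_thresholds()], or any data frame
#'   with `location_id`, `tmax_threshold`, `tmin_threshold`.
#' @param min_duration Minimum event length in days (default 2; 3 or 4 are
#'   common sensitivity choices).
#' @param season_months Warm-season months; days outside them are dropped
#'   before run detection.
#'
#' @return A tibble of events: `location_id`, `start_date`, `end_date`,
#'   `duration`, `event_type` (`"daytime_accentuated"` or
#'   `"nighttime_accentuated"`), `cum_excess_tmax`, `cum_excess_tmin`
#'   (degree-days).
#' @export
detect_heatwave_events <- function(climate, thresholds, min_duration = 2,
                                   season_months = .default_season) {
  validate_climate(climate)
  if (min_duration < 1) abort("`min_duration` must be >= 1.")
  missing_locs <- setdiff(unique(climate$location_id), thresholds$location_id)
  if (length(missing_locs) > 0) {
    abort(paste0("Thresholds missing for location(s): ",
                 paste(missing_locs, collapse = ", ")))
  }

  x <- climate %>%
    filter(date_month(.data$date) %in% season_months) %>%
    left_join(
      select(as_tibble(thresholds), "location_id", "tmax_threshold",
             "tmin_threshold"),
      by = "location_id"
    ) %>%
    arrange(.data$location_id, .data$date)

  if (nrow(x) == 0) return(empty_events())

  exceed <- x$tmax > x$tmax_threshold | x$tmin > x$tmin_threshold
  if (!any(exceed)) return(empty_events())
  # a new run starts at any location change, any date gap, any season-year
  # change, or any transition into exceedance
  season_year <- date_year(x$date)
  new_block <- c(TRUE,
                 x$location_id[-1] != x$location_id[-nrow(x)] |
                   diff(x$date) != 1 |
                   diff(season_year) != 0)
  run_id <- cumsum(new_block | c(TRUE, !exceed[-nrow(x)]))
  x$run_id <- run_id
  x$exceed <- exceed

  ev <- x %>%
    filter(.data$exceed) %>%
    group_by(.data$location_id, .data$run_id) %>%
    summarise(
      start_date = min(.data$date),
      end_date = max(.data$date),
      duration = dplyr::n(),
      cum_excess_tmax = sum(pmax(0, .data$tmax - .data$tmax_threshold)),
      cum_excess_tmin = sum(pmax(0, .data$tmin - .data$tmin_threshold)),
      .groups = "drop"
    ) %>%
    filter(.data$duration >= min_duration) %>%
    mutate(
      event_type = if_else(.data$cum_excess_tmax > .data$cum_excess_tmin,
                           "daytime_accentuated", "nighttime_accentuated")
    ) %>%
    select("location_id", "start_date", "end_date", "duration", "event_type",
           "cum_excess_tmax", "cum_excess_tmin") %>%
    arrange(.data$location_id, .data$start_date)
  ev
}

empty_events <- function() {
  tibble(
    location_id = character(), start_date = as.Date(character()),
    end_date = as.Date(character()), duration = integer(),
    event_type = character(), cum_excess_tmax = numeric(),
    cum_excess_tmin = numeric()
  )
}

#' Compute daily daytime and nighttime heatwave indices
#'
#' On every day belonging to a detected heatwave event, the daytime HWI is
#' the excess of Tmax over its threshold and the nighttime HWI the excess of
#' Tmin over its threshold (floored at zero). Both indices are zero on
#' non-heatwave days, including isolated exceedance days that did not form
#' an event. Binary flags mark membership in a daytime- or
#' nighttime-accentuated event; at most one flag is set per day.
#'
#' Both daily indices are computed on every heatwave day regardless of the
#' containing event's classification, so a day inside a daytime-accentuated
#' event can carry a positive nighttime HWI. Set `zero_off_type = TRUE` to
#' zero the index that does not match the event type.
#'
#' @inheritParams detect_heatwave_events
#' @param events Output of [detect_heatwave_events()] on the same climate
#'   and thresholds.
#' @param zero_off_type If `TRUE`, zero the off-type daily index within each
#'   event (default `FALSE`).
#'
#' @return A tibble with one row per season location-day: `location_id`,
#'   `date`, `dhwi`, `nhwi` (degrees C), `dhw_flag`, `nhw_flag` (0/1), plus
#'   `rh` when present in `climate`.
#' @export
compute_daily_hwi <- function(climate, thresholds, events,
                              season_months = .default_season,
                              zero_off_type = FALSE) {
  x <- climate %>%
    filter(date_month(.data$date) %in% season_months) %>%
    left_join(
      select(as_tibble(thresholds), "location_id", "tmax_threshold",
             "tmin_threshold"),
      by = "location_id"
    )

  if (nrow(events) > 0) {
    ev_days <- events %>%
      mutate(.ev = dplyr::row_number()) %>%
      group_by(.data$.ev) %>%
      reframe_days() %>%
      ungroup()
    dup <- ev_days %>% count(.data$location_id, .data$date) %>% filter(n > 1)
    if (nrow(dup) > 0) {
      abort(paste0("Overlapping events for location ", dup$location_id[1],
                   " around ", format(dup$date[1]),
                   " (event construction bug)."))
    }
    x <- left_join(x, ev_days, by = c("location_id", "date"))
  } else {
    x$event_type <- NA_character_
  }

  in_event <- !is.na(x$event_type)
  out <- x %>%
    mutate(
      dhwi = if_else(in_event, pmax(0, .data$tmax - .data$tmax_threshold), 0),
      nhwi = if_else(in_event, pmax(0, .data$tmin - .data$tmin_threshold), 0),
      dhw_flag = as.integer(in_event & .data$event_type == "daytime_accentuated"),
      nhw_flag = as.integer(in_event & .data$event_type == "nighttime_accentuated")
    )
  if (zero_off_type) {
    out <- out %>%
      mutate(
        dhwi = if_else(in_event & .data$nhw_flag == 1L, 0, .data$dhwi),
        nhwi = if_else(in_event & .data$dhw_flag == 1L, 0, .data$nhwi)
      )
  }
  keep <- c("location_id", "date", "dhwi", "nhwi", "dhw_flag", "nhw_flag")
  if ("rh" %in% names(out)) keep <- c(keep, "rh")
  out %>% select(all_of(keep)) %>% arrange(.data$location_id, .data$date)
}

reframe_days <- function(ev) {
  dplyr::reframe(ev,
    location_id = .data$location_id,
    date = seq(.data$start_date, .data$end_date, by = "day"),
    event_type = .data$event_type
  )
}
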