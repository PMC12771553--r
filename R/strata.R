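#' Assign time-stratified case-crossover strata
#'
#' Each location-day is assigned to the stratum of all days in the same
#' location, calendar year, calendar month and day of week. Days sharing a
#' stratum are mutual case and control days; a stratum always contains 4 or
#' 5 calendar days. Weekdays follow the ISO convention (Monday = 1).
#'
#' @param dates A Date vector.
#' @param locations A vector of location identifiers, recycled against
#'   `dates` (or same length).
#'
#' @return A tibble with `location_id`, `date`, `year`, `month`, `weekday`
#'   and the serialized `stratum` key `location|year|month|weekday`.
#' @export
build_strata <- function(dates, locations) {
  if (!inherits(dates, "Date")) abort("`dates` must be a Date vector.")
  tibble(location_id = locations, date = dates) %>%
    mutate(
      year = date_year(.data$date),
      month = date_month(.data$date),
      weekday = iso_wday(.data$date),
      stratum = paste(.data$location_id, .data$year, .data$month,
                      .data$weekday, sep = "|")
    )
}

#' Filter health records to a subgroup
#'
#' Restricts daily count records to one level (or an intersection of levels
#' across attributes) of the stratifying variables, leaving counts
#' untouched. Levels partition records, so complementary calls partition
#' totals.
#'
#' @param health Health-count tibble with `location_id`, `date`, `cause`,
#'   `count` and attribute columns such as `sex`, `age_group`,
#'   `race_ethnicity`, `region_flag`.
#' @param ... Named attribute = level pairs, e.g. `sex = "female"`,
#'   `age_group = "0-14"`. Several pairs select their intersection.
#'
#' @return The filtered tibble.
#' @export
filter_subgroup <- function(health, ...) {
  sel <- list(...)
  if (length(sel) == 0) return(health)
  if (is.null(names(sel)) || any(names(sel) == "")) {
    abort("All subgroup selectors must be named, e.g. sex = \"female\".")
  }
  for (attr_name in names(sel)) {
    if (!attr_name %in% names(health)) {
      abort(paste0("Attribute `", attr_name, "` not present in health records."))
    }
    lev <- sel[[attr_name]]
    valid <- unique(health[[attr_name]])
    unknown <- setdiff(lev, valid)
    if (length(unknown) > 0) {
      abort(paste0("Unknown level(s) ", paste(unknown, collapse = ", "),
                   " for `", attr_name, "`; valid levels: ",
                   paste(sort(valid), collapse = ", "), "."))
    }
    health <- health[health[[attr_name]] %in% lev, , drop = FALSE]
  }
  health
}

#' Assemble a time-stratified case-crossover analysis panel
#'
#' Joins daily counts for one cause (optionally one subgroup) to the daily
#' heatwave-index exposure series, materializing zero-count days so that
#' every exposure-covered location-day appears exactly once. Rows whose
#' exposure is missing are dropped and reported via the `dropped_days`
#' attribute.
#'
#' @param health Health-count tibble (see [filter_subgroup()]).
#' @param exposure Daily exposure tibble from [compute_daily_hwi()].
#' @param cause Cause label to select; `NULL` keeps all causes pooled.
#' @param ... Subgroup selectors passed to [filter_subgroup()].
#'
#' @return A panel tibble with the stratum key columns, `date`, `count`,
#'   `dhwi`, `nhwi`, `dhw_flag`, `nhw_flag` (and `rh` when available).
#' @export
assemble_panel <- function(health, exposure, cause = NULL, ...) {
  if (!is.null(cause)) {
    if (!cause %in% unique(health$cause)) {
      abort(paste0("Cause `", cause, "` not present; available: ",
                   paste(sort(unique(health$cause)), collapse = ", "), "."))
    }
    health <- filter(health, .data$cause == .env$cause)
  }
  health <- filter_subgroup(health, ...)
  if (any(health$count < 0)) abort("Negative counts in health records.")

  outside <- anti_join(health, exposure, by = c("location_id", "date"))
  if (nrow(outside) > 0) {
    abort(paste0(
      "Health records dated outside exposure coverage, e.g. location ",
      outside$location_id[1], " on ", format(outside$date[1]),
      " (", nrow(outside), " record(s))."
    ))
  }

  counts <- health %>%
    group_by(.data$location_id, .data$date) %>%
    summarise(count = sum(.data$count), .groups = "drop")

  expo_cols <- intersect(c("dhwi", "nhwi", "dhw_flag", "nhw_flag", "rh"),
                         names(exposure))
  panel <- exposure %>%
    left_join(counts, by = c("location_id", "date")) %>%
    mutate(count = tidyr::replace_na(.data$count, 0))

  dropped <- panel %>% filter(is.na(.data$dhwi) | is.na(.data$nhwi))
  if (nrow(dropped) > 0) {
    inform(paste0("Dropping ", nrow(dropped),
                  " location-day(s) with missing exposure."))
    panel <- panel %>% filter(!is.na(.data$dhwi) & !is.na(.data$nhwi))
  }

  strata <- build_strata(panel$date, panel$location_id)
  panel <- panel %>%
    mutate(year = strata$year, month = strata$month,
           weekday = strata$weekday, stratum = strata$stratum) %>%
    select(all_of(c("stratum", "location_id", "year", "month", "weekday",
                    "date", "count", expo_cols))) %>%
    arrange(.data$location_id, .data$date)
  attr(panel, "dropped_days") <- nrow(dropped)
  attr(panel, "cause") <- cause %||% "all"
  panel
}
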