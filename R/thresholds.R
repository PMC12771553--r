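#' Compute climatological heatwave thresholds
#'
#' Per-location percentile thresholds for daily maximum and minimum
#' temperature, pooled over all warm-season days of a reference climatology.
#' The default follows the common convention for heatwave definitions: the
#' 95th percentile of daily Tmax and of daily Tmin over May--October of a
#' 30-year reference period.
#'
#' Percentiles use linear interpolation between closest order statistics
#' (position `h = (n - 1) * p + 1`, i.e. [stats::quantile()] type 7). All
#' season-days of all reference years are pooled; no day-of-year window is
#' applied.
#'
#' @param climate A data frame of daily climate records with columns
#'   `location_id`, `date` (Date), `tmax`, `tmin` (degrees C).
#' @param percentile_level Percentile for the thresholds, in (0, 1).
#'   Default 0.95; 0.90 reproduces a common sensitivity analysis.
#' @param reference_period Integer vector of length 2, first and last
#'   calendar year of the reference climatology (inclusive). `NULL` uses
#'   every year present.
#' @param season_months Integer months defining the warm season
#'   (default May--October).
#'
#' @return A tibble with one row per location: `location_id`,
#'   `tmax_threshold`, `tmin_threshold`, plus attributes recording
#'   `percentile_level`, `reference_period` and `season_months`.
#' @examples
#' clim <- tibble::tibble(
#'   location_id = "A",
#'   date = seq(as.Date("1990-05-01"), as.Date("1990-08-31"), by = "day"),
#'   tmax = 30, tmin = 18
#' )
#' compute_thresholds(clim, reference_period = c(1990, 1990))
#' @export
compute_thresholds <- function(climate,
                               percentile_level = 0.95,
                               reference_period = NULL,
                               season_months = .default_season) {
  validate_climate(climate)
  if (!is.numeric(percentile_level) || length(percentile_level) != 1 ||
      percentile_level <= 0 || percentile_level >= 1) {
    abort("`percentile_level` must be a single number in (0, 1).")
  }
  yrs <- date_year(climate$date)
  keep <- date_month(climate$date) %in% season_months
  if (!is.null(reference_period)) {
    keep <- keep & yrs >= reference_period[1] & yrs <= reference_period[2]
  }
  ref <- climate[keep, , drop = FALSE]

  missing_locs <- setdiff(unique(climate$location_id), unique(ref$location_id))
  if (length(missing_locs) > 0) {
    abort(paste0(
      "No season-days in the reference period for location(s): ",
      paste(missing_locs, collapse = ", ")
    ))
  }

  out <- ref %>%
    group_by(.data$location_id) %>%
    summarise(
      tmax_threshold = unname(quantile(.data$tmax, percentile_level,
                                       type = 7, names = FALSE)),
      tmin_threshold = unname(quantile(.data$tmin, percentile_level,
                                       type = 7, names = FALSE)),
      .groups = "drop"
    )
  if (any(!is.finite(out$tmax_threshold)) || any(!is.finite(out$tmin_threshold))) {
    abort("Non-finite threshold computed; check input temperatures.")
  }
  attr(out, "percentile_level") <- percentile_level
  attr(out, "reference_period") <- reference_period %||% range(yrs[keep])
  attr(out, "season_months") <- season_months
  class(out) <- c("hw_thresholds", class(out))
  out
}

validate_climate <- function(climate, require_rh = FALSE) {
  needed <- c("location_id", "date", "tmax", "tmin")
  missing <- setdiff(needed, names(climate))
  if (length(missing) > 0) {
    abort(paste0("Climate data missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (!inherits(climate$date, "Date")) {
    abort("`date` must be a Date column (ISO 8601).")
  }
  bad <- which(climate$tmin > climate$tmax)
  if (length(bad) > 0) {
    ex <- climate[bad[1], ]
    abort(paste0(
      "tmin > tmax for ", length(bad), " row(s); first offender: location ",
      ex$location_id, ", date ", format(ex$date), "."
    ))
  }
  dup <- anyDuplicated(paste(climate$location_id,
                             as.integer(unclass(climate$date))))
  if (dup > 0) {
    abort(paste0("Duplicate location-days in climate data, e.g. location ",
                 climate$location_id[dup], " on ",
                 format(climate$date[dup]), "."))
  }
  if (require_rh && !"rh" %in% names(climate)) {
    abort("Relative humidity column `rh` required but absent.")
  }
  invisible(climate)
}
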