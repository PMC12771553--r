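#' Read and write the pipeline's delimited-text tables
#'
#' All tables are plain CSV with a header row and ISO-8601 dates. Readers
#' validate the header and reject structurally invalid rows (negative
#' counts, `tmin > tmax`, unparseable dates) with the file, row and column
#' named; writers round-trip numeric values to full double precision.
#'
#' @param path File path.
#' @name nightheat-io
NULL

.read_checked <- function(path, required, date_cols = "date") {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    abort(paste0(path, ": missing column(s) ",
                 paste(missing, collapse = ", "), "."))
  }
  for (dc in intersect(date_cols, names(x))) {
    if (!inherits(x[[dc]], "Date")) {
      parsed <- as.Date(as.character(x[[dc]]), format = "%Y-%m-%d")
      bad <- which(is.na(parsed) & !is.na(x[[dc]]))
      if (length(bad) > 0) {
        abort(paste0(path, ": unparseable date in column `", dc,
                     "`, data row ", bad[1], "."))
      }
      x[[dc]] <- parsed
    }
  }
  x
}

#' @rdname nightheat-io
#' @return `read_climate()`: validated climate tibble.
#' @export
read_climate <- function(path) {
  x <- .read_checked(path, c("location_id", "date", "tmax", "tmin"))
  bad <- which(x$tmin > x$tmax)
  if (length(bad) > 0) {
    abort(paste0(path, ": tmin > tmax at data row ", bad[1], " (location ",
                 x$location_id[bad[1]], ", date ",
                 format(x$date[bad[1]]), ")."))
  }
  x$location_id <- as.character(x$location_id)
  validate_climate(x)
  x
}

#' @rdname nightheat-io
#' @return `read_health()`: validated health-count tibble.
#' @export
read_health <- function(path) {
  x <- .read_checked(path, c("location_id", "date", "cause", "count"))
  bad <- which(x$count < 0 | x$count != floor(x$count))
  if (length(bad) > 0) {
    abort(paste0(path, ": invalid count `", x$count[bad[1]],
                 "` at data row ", bad[1], " (column `count`)."))
  }
  x$location_id <- as.character(x$location_id)
  x
}

#' @rdname nightheat-io
#' @return `read_exposure()`: daily HWI exposure tibble.
#' @export
read_exposure <- function(path) {
  x <- .read_checked(path, c("location_id", "date", "dhwi", "nhwi",
                             "dhw_flag", "nhw_flag"))
  if (any(x$dhwi < 0, na.rm = TRUE) || any(x$nhwi < 0, na.rm = TRUE)) {
    abort(paste0(path, ": negative HWI values."))
  }
  x$location_id <- as.character(x$location_id)
  x
}

#' @rdname nightheat-io
#' @param x Table to write.
#' @export
write_table <- function(x, path) {
  readr::write_csv(x, path, progress = FALSE)
  invisible(path)
}

#' Extract location series from a gridded climate array
#'
#' Maps locations onto cells of a gridded daily temperature product: the
#' value at a location is the value of its mapped cell (no interpolation).
#' Arrays are indexed `[cell, day]`.
#'
#' @param tmax,tmin Numeric matrices, cells in rows and days in columns.
#' @param dates Date vector, one per column.
#' @param mapping Data frame with `location_id` and `cell` (row index into
#'   the arrays).
#' @return A daily climate tibble usable by [compute_thresholds()].
#' @export
extract_gridded <- function(tmax, tmin, dates, mapping) {
  if (!all(c("location_id", "cell") %in% names(mapping))) {
    abort("`mapping` needs columns `location_id` and `cell`.")
  }
  if (ncol(tmax) != length(dates) || !all(dim(tmax) == dim(tmin))) {
    abort("Array dimensions must be [cell, day] matching `dates`.")
  }
  bad <- mapping$cell < 1 | mapping$cell > nrow(tmax)
  if (any(bad)) {
    abort(paste0("Mapping cell index out of range for location(s): ",
                 paste(mapping$location_id[bad], collapse = ", ")))
  }
  purrr::map_dfr(seq_len(nrow(mapping)), function(i) {
    tibble(location_id = as.character(mapping$location_id[i]), date = dates,
           tmax = tmax[mapping$cell[i], ], tmin = tmin[mapping$cell[i], ])
  }) %>% arrange(.data$location_id, .data$date)
}
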