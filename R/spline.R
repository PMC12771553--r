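#' Fit a natural-cubic-spline exposure-response model
#'
#' Replaces the linear daytime and nighttime HWI terms by natural cubic
#' spline bases (linear beyond the boundary knots) with two interior knots,
#' by default at the 10th and 50th percentiles of the positive
#' (heatwave-day) HWI values of each index. Boundary knots sit at 0 and the
#' observed maximum, so the fitted exposure-response curve is anchored at
#' log relative risk 0 at HWI = 0 by construction.
#'
#' Interior knots are placed over heatwave-day values because the HWI
#' distribution is a point mass at zero on non-heatwave days: pooling zeros
#' would collapse both knots to 0. Set `knots_include_zeros = TRUE` to use
#' the full distribution instead.
#'
#' @inheritParams fit_conditional_poisson
#' @param knot_percentiles Interior knot percentiles, strictly increasing in
#'   (0, 1). Default `c(0.10, 0.50)`.
#' @param knots_include_zeros Place knots on the full HWI distribution
#'   including zero days (default `FALSE`).
#' @param curve_points Number of grid points per exposure-response curve.
#'
#' @return An `hw_fit` whose `extra$curves` is a tibble of predicted
#'   log relative risk (`log_rr`, with `se` and 95% bounds) on a grid of
#'   HWI values for each exposure, anchored at 0 at HWI = 0, and
#'   `extra$knots` records the interior knots used.
#' @export
fit_spline_model <- function(panel,
                             knot_percentiles = c(0.10, 0.50),
                             knots_include_zeros = FALSE,
                             covariates = character(),
                             dispersion_floor = 0,
                             max_iter = 100, tol = 1e-10,
                             curve_points = 50) {
  if (any(diff(knot_percentiles) <= 0) ||
      any(knot_percentiles <= 0 | knot_percentiles >= 1)) {
    abort("`knot_percentiles` must be strictly increasing within (0, 1).")
  }
  basis_for <- function(v, nm) {
    pool <- if (knots_include_zeros) v else v[v > 0]
    if (length(unique(pool)) < length(knot_percentiles) + 2) {
      abort(paste0("Too few distinct positive ", nm,
                   " values to place spline knots; use a linear form or ",
                   "coarser knots."))
    }
    kn <- unname(quantile(pool, knot_percentiles, type = 7))
    if (any(duplicated(kn))) {
      abort(paste0("Coincident spline knots for ", nm, " (",
                   paste(format(kn), collapse = ", "),
                   "); choose different knot percentiles or pool zeros."))
    }
    bk <- c(0, max(v))
    B <- splines::ns(v, knots = kn, Boundary.knots = bk)
    colnames(B) <- paste0(nm, "_ns", seq_len(ncol(B)))
    list(B = B, knots = kn, boundary = bk)
  }
  bd <- basis_for(panel$dhwi, "dhwi")
  bn <- basis_for(panel$nhwi, "nhwi")
  X <- cbind(bd$B, bn$B)
  if (length(covariates) > 0) {
    X <- cbind(X, as.matrix(panel[, covariates, drop = FALSE]))
  }

  fit <- fit_conditional_core(
    y = panel$count, X = X, stratum = panel$stratum,
    exposure_form = "spline_hwi", dispersion_floor = dispersion_floor,
    max_iter = max_iter, tol = tol,
    extra = list(knots = list(dhwi = bd$knots, nhwi = bn$knots))
  )

  curve_one <- function(b, nm) {
    grid <- seq(0, b$boundary[2], length.out = curve_points)
    Bg <- splines::ns(grid, knots = b$knots, Boundary.knots = b$boundary)
    B0 <- splines::ns(0, knots = b$knots, Boundary.knots = b$boundary)
    D <- sweep(Bg, 2, as.vector(B0))  # difference from the HWI = 0 anchor
    cols <- paste0(nm, "_ns", seq_len(ncol(Bg)))
    bet <- fit$beta[cols]
    V <- fit$vcov[cols, cols, drop = FALSE]
    lrr <- as.vector(D %*% bet)
    se <- sqrt(pmax(0, rowSums((D %*% V) * D)))
    tibble(exposure = nm, hwi = grid, log_rr = lrr, se = se,
           ci_low = lrr - qnorm(0.975) * se,
           ci_high = lrr + qnorm(0.975) * se)
  }
  fit$extra$curves <- bind_rows(curve_one(bd, "dhwi"), curve_one(bn, "nhwi"))
  fit
}

#' Fit a single-lag conditional quasi-Poisson model
#'
#' Re-joins the exposure series at `date - lag` so that day *t*'s counts are
#' modelled against the HWIs observed `lag` days earlier, then fits the
#' usual conditional model. Separate single-lag models (lag 0 through 6) are
#' the conventional way to trace how an acute effect decays after exposure.
#' Rows whose lagged date falls outside exposure coverage are dropped.
#'
#' @inheritParams fit_conditional_poisson
#' @param lag Integer lag in days, 0 to 6. Lag 0 reproduces the unlagged fit.
#' @return An `hw_fit` (see [fit_conditional_poisson()]); `extra$lag`
#'   records the lag.
#' @export
fit_lag_model <- function(panel, lag,
                          exposure_form = c("linear_hwi", "binary_hw"),
                          covariates = character(),
                          dispersion_floor = 0) {
  exposure_form <- match.arg(exposure_form)
  if (length(lag) != 1 || lag != as.integer(lag) || lag < 0 || lag > 6) {
    abort("`lag` must be a single integer between 0 and 6.")
  }
  expo_cols <- c("dhwi", "nhwi", "dhw_flag", "nhw_flag")
  lagged <- panel %>%
    select(all_of(c("location_id", "date", expo_cols))) %>%
    mutate(date = .data$date + lag)
  lp <- panel %>%
    select(-all_of(expo_cols)) %>%
    dplyr::inner_join(lagged, by = c("location_id", "date"))
  if (nrow(lp) == 0) abort("No rows remain after lagging exposure.")
  fit <- fit_conditional_poisson(lp, exposure_form = exposure_form,
                                 covariates = covariates,
                                 dispersion_floor = dispersion_floor)
  fit$extra$lag <- lag
  fit
}

#' Fit the binary heatwave-event model
#'
#' Secondary analysis in which the continuous HWIs are replaced by binary
#' indicators of daytime- and nighttime-accentuated event days, so the
#' coefficients measure the percent change per heatwave day rather than per
#' degree Celsius.
#'
#' @inheritParams fit_conditional_poisson
#' @return An `hw_fit` with terms `dhw_flag` and `nhw_flag`.
#' @export
fit_binary_model <- function(panel, covariates = character(),
                             dispersion_floor = 0) {
  fit_conditional_poisson(panel, exposure_form = "binary_hw",
                          covariates = covariates,
                          dispersion_floor = dispersion_floor)
}
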