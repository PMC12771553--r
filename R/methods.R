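#' Tidy a conditional quasi-Poisson fit
#'
#' One row per exposure term with log-scale coefficient, dispersion-scaled
#' standard error, and the percent-change transform with its Wald 95%
#' interval and p-value.
#'
#' @param x An `hw_fit`.
#' @param ... Unused.
#' @return A tibble: `term`, `estimate`, `std_error`, `percent_change`,
#'   `ci_low`, `ci_high`, `p_value`.
#' @exportS3Method generics::tidy
#' @export
tidy.hw_fit <- function(x, ...) {
  se <- sqrt(diag(x$vcov))
  pc <- percent_change(x$beta, se, label = x$terms)
  tibble(
    term = x$terms,
    estimate = unname(x$beta),
    std_error = unname(se),
    percent_change = unname(pc$percent_change),
    ci_low = unname(pc$ci_low),
    ci_high = unname(pc$ci_high),
    p_value = unname(pc$p_value)
  )
}

#' One-row summary of a conditional quasi-Poisson fit
#'
#' @param x An `hw_fit`.
#' @param ... Unused.
#' @return A tibble with `dispersion`, `n_informative_strata`,
#'   `n_rows_used`, `residual_df`, `log_cond_lik`, `converged`,
#'   `iterations`, `exposure_form`.
#' @exportS3Method generics::glance
#' @export
glance.hw_fit <- function(x, ...) {
  tibble(
    dispersion = x$dispersion,
    n_informative_strata = x$n_informative_strata,
    n_rows_used = x$n_rows_used,
    residual_df = x$residual_df,
    log_cond_lik = x$log_cond_lik,
    converged = x$converged,
    iterations = x$iterations,
    exposure_form = x$exposure_form
  )
}

#' @export
print.hw_fit <- function(x, ...) {
  cat("Conditional quasi-Poisson case-crossover fit (",
      x$exposure_form, ")\n", sep = "")
  cat("  informative strata: ", x$n_informative_strata,
      ";  rows used: ", x$n_rows_used,
      ";  dispersion phi = ", format(x$dispersion, digits = 4), "\n",
      sep = "")
  print(as.data.frame(tidy(x)), digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
coef.hw_fit <- function(object, ...) object$beta

#' @export
vcov.hw_fit <- function(object, ...) object$vcov

#' Plot percent-change estimates with 95% intervals
#'
#' Forest-style plot of a tidied estimate table (columns `term` or `label`,
#' `percent_change`, `ci_low`, `ci_high`).
#'
#' @param estimates A tibble as returned by [tidy.hw_fit()].
#' @return A ggplot object.
#' @export
plot_estimates <- function(estimates) {
  lab <- if ("term" %in% names(estimates)) "term" else "label"
  ggplot2::ggplot(estimates,
                  ggplot2::aes(x = .data$percent_change,
                               y = .data[[lab]])) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high)) +
    ggplot2::labs(x = "Percent change per unit exposure (95% CI)",
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn plot_estimates autoplot method for `hw_fit` objects.
#' @param object An `hw_fit`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.hw_fit <- function(object, ...) {
  if (object$exposure_form == "spline_hwi" &&
      !is.null(object$extra$curves)) {
    return(plot_exposure_response(object))
  }
  plot_estimates(tidy(object))
}

#' Plot a spline exposure-response curve
#'
#' Log relative risk against HWI for each exposure, anchored at 0, with the
#' pointwise 95% band.
#'
#' @param fit An `hw_fit` from [fit_spline_model()].
#' @return A ggplot object.
#' @export
plot_exposure_response <- function(fit) {
  stopifnot(!is.null(fit$extra$curves))
  ggplot2::ggplot(fit$extra$curves,
                  ggplot2::aes(x = .data$hwi, y = .data$log_rr)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low,
                                      ymax = .data$ci_high),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::facet_wrap(~exposure, scales = "free_x") +
    ggplot2::labs(x = "Heatwave index (°C)", y = "Log relative risk") +
    ggplot2::theme_minimal()
}

#' Plot annual attributable numbers by heatwave type
#'
#' Stacked annual attributable counts for daytime- and
#' nighttime-accentuated heatwaves, with the Monte Carlo interval of the
#' total.
#'
#' @param attribution Output of [attribution_uncertainty()].
#' @return A ggplot object.
#' @export
plot_attribution <- function(attribution) {
  comp <- attribution %>% filter(.data$component != "total")
  tot <- attribution %>% filter(.data$component == "total")
  ggplot2::ggplot(comp, ggplot2::aes(x = factor(.data$year), y = .data$an,
                                     fill = .data$component)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(
      data = tot,
      ggplot2::aes(x = factor(.data$year), ymin = .data$ci_low,
                   ymax = .data$ci_high),
      inherit.aes = FALSE, width = 0.25
    ) +
    ggplot2::labs(x = "Year", y = "Attributable acute care utilizations",
                  fill = "Heatwave type") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
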