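#' Fit a conditional quasi-Poisson case-crossover model
#'
#' Maximizes the Poisson likelihood of daily counts with one intercept per
#' case-crossover stratum, eliminating the stratum intercepts by
#' conditioning on stratum totals: given its total, the vector of counts in
#' a stratum is multinomial with day probabilities
#' \eqn{p_i = e^{x_i'\beta} / \sum_j e^{x_j'\beta}}, so the conditional
#' log-likelihood depends only on the exposure coefficients. The resulting
#' estimates are numerically identical to a Poisson fit with explicit
#' stratum dummies. Standard errors are scaled by the square root of a
#' Pearson dispersion factor (quasi-Poisson).
#'
#' Strata with zero total count, or in which every design column is
#' constant, carry no information about the exposure coefficients and are
#' excluded before fitting.
#'
#' @param panel Analysis panel from [assemble_panel()].
#' @param exposure_form One of `"linear_hwi"` (default; per-degree-C daytime
#'   and nighttime HWI effects), `"binary_hw"` (event-membership flags), or
#'   `"spline_hwi"` (see [fit_spline_model()]).
#' @param covariates Optional character vector of additional linear
#'   covariate columns (e.g. `"rh"` for a relative-humidity adjustment).
#' @param dispersion_floor Lower bound applied to the dispersion factor
#'   before SE scaling. Default 0 (pure quasi-likelihood, no floor); set to
#'   1 to never deflate Poisson standard errors.
#' @param max_iter,tol Newton-Raphson controls: iteration cap and relative
#'   log-likelihood convergence tolerance.
#'
#' @return An object of class `hw_fit` with elements `beta`, `vcov`
#'   (dispersion-scaled), `vcov_unscaled`, `dispersion`,
#'   `n_informative_strata`, `n_rows_used`, `converged`, `iterations`,
#'   `exposure_form`, `terms`. Methods: [tidy.hw_fit()], [glance.hw_fit()],
#'   `print`.
#' @seealso [percent_change()], [fit_binary_model()], [fit_lag_model()],
#'   [fit_spline_model()]
#' @export
fit_conditional_poisson <- function(panel,
                                    exposure_form = c("linear_hwi",
                                                      "binary_hw",
                                                      "spline_hwi"),
                                    covariates = character(),
                                    dispersion_floor = 0,
                                    max_iter = 100, tol = 1e-10) {
  exposure_form <- match.arg(exposure_form)
  if (exposure_form == "spline_hwi") {
    return(fit_spline_model(panel, covariates = covariates,
                            dispersion_floor = dispersion_floor,
                            max_iter = max_iter, tol = tol))
  }
  terms <- switch(exposure_form,
                  linear_hwi = c("dhwi", "nhwi"),
                  binary_hw = c("dhw_flag", "nhw_flag"))
  terms <- c(terms, covariates)
  missing <- setdiff(terms, names(panel))
  if (length(missing) > 0) {
    abort(paste0("Panel missing model column(s): ",
                 paste(missing, collapse = ", ")))
  }
  X <- as.matrix(panel[, terms, drop = FALSE])
  storage.mode(X) <- "double"
  fit_conditional_core(y = panel$count, X = X, stratum = panel$stratum,
                       exposure_form = exposure_form,
                       dispersion_floor = dispersion_floor,
                       max_iter = max_iter, tol = tol)
}

# Newton-Raphson on the stratum-conditioned (multinomial) log-likelihood.
fit_conditional_core <- function(y, X, stratum, exposure_form,
                                 dispersion_floor = 0,
                                 max_iter = 100, tol = 1e-10,
                                 extra = list()) {
  stopifnot(length(y) == nrow(X), length(stratum) == nrow(X))
  sid <- match(stratum, unique(stratum))

  # drop uninformative strata: zero total, or all design columns constant
  tot <- rowsum(y, sid)
  colmax <- rowsum_max_abs_dev(X, sid)
  informative_ids <- which(tot[, 1] > 0 & colmax > 1e-12)
  keep <- sid %in% informative_ids
  if (!any(keep)) {
    abort("model unidentifiable: no informative strata (need total count > 0 and within-stratum exposure variation).")
  }
  y <- y[keep]; X <- X[keep, , drop = FALSE]
  sid <- match(sid[keep], unique(sid[keep]))
  n_strata <- max(sid)
  p <- ncol(X)

  # rank check on within-stratum centered design
  Xc <- X - rowsum(X, sid)[sid, , drop = FALSE] / as.vector(table(sid))[sid]
  if (qr(Xc)$rank < p) {
    abort("model unidentifiable: design matrix rank-deficient after stratum centering.")
  }

  stot <- rowsum(y, sid)[, 1]
  beta <- rep(0, p)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0
  for (iter in seq_len(max_iter)) {
    eta <- as.vector(X %*% beta)
    w <- exp(eta - ave_max(eta, sid))  # log-sum-exp guard, cancels in pr
    denom <- rowsum(w, sid)[, 1]
    pr <- w / denom[sid]
    mu <- stot[sid] * pr
    ll <- sum(y * log(pr))
    grad <- crossprod(X, y - mu)[, 1]
    Xp <- rowsum(X * mu, sid)  # per-stratum sum of mu_i x_i
    H <- crossprod(X * mu, X) - crossprod(Xp / sqrt(stot), Xp / sqrt(stot))
    step <- tryCatch(solve(H, grad), error = function(e) {
      abort(paste0("Newton step failed (singular information): ",
                   conditionMessage(e)))
    })
    # step halving if likelihood decreases
    shrink <- 1
    repeat {
      beta_new <- beta + shrink * step
      etan <- as.vector(X %*% beta_new)
      wn <- exp(etan - ave_max(etan, sid))
      prn <- wn / rowsum(wn, sid)[, 1][sid]
      ll_new <- sum(y * log(prn))
      if (is.finite(ll_new) && (ll_new >= ll || shrink < 1e-8)) break
      shrink <- shrink / 2
    }
    beta <- beta_new
    if (is.finite(ll_old) && abs(ll_new - ll_old) <
        tol * (abs(ll_old) + tol)) {
      converged <- TRUE
      ll_old <- ll_new
      break
    }
    ll_old <- ll_new
  }
  if (!converged && iter >= max_iter) {
    eta <- as.vector(X %*% beta)
    w <- exp(eta - ave_max(eta, sid))
    mu <- stot[sid] * (w / rowsum(w, sid)[, 1][sid])
    gn <- sqrt(sum(crossprod(X, y - mu)^2))
    abort(paste0("Conditional Poisson fit did not converge in ", max_iter,
                 " iterations (gradient norm ", format(gn), ")."))
  }

  # fitted means and observed information at the optimum
  eta <- as.vector(X %*% beta)
  w <- exp(eta - ave_max(eta, sid))
  pr <- w / rowsum(w, sid)[, 1][sid]
  mu <- stot[sid] * pr
  Xp <- rowsum(X * mu, sid)
  H <- crossprod(X * mu, X) - crossprod(Xp / sqrt(stot), Xp / sqrt(stot))
  V0 <- solve(H)
  V0 <- (V0 + t(V0)) / 2
  names(beta) <- colnames(X)
  dimnames(V0) <- list(colnames(X), colnames(X))

  df <- length(y) - n_strata - p
  if (df > 0) {
    phi <- sum((y - mu)^2 / mu) / df
    phi_eff <- max(phi, dispersion_floor)
  } else {
    # no residual degrees of freedom: report unscaled (Poisson) SEs
    phi <- NA_real_
    phi_eff <- 1
  }

  structure(list(
    beta = beta,
    vcov = V0 * phi_eff,
    vcov_unscaled = V0,
    dispersion = phi,
    dispersion_floor = dispersion_floor,
    n_informative_strata = n_strata,
    n_rows_used = length(y),
    log_cond_lik = ll_old,
    converged = converged,
    iterations = iter,
    exposure_form = exposure_form,
    terms = colnames(X),
    fitted = mu,
    residual_df = df,
    extra = extra
  ), class = "hw_fit")
}

# per-group running max for log-sum-exp stabilization
ave_max <- function(x, g) {
  m <- vapply(split(x, g), max, numeric(1))
  m[as.character(g)]
}

# max absolute deviation from the stratum mean, per column, collapsed to a
# single "any variation" score per stratum
rowsum_max_abs_dev <- function(X, sid) {
  ns <- as.vector(table(sid))
  means <- rowsum(X, sid) / ns
  dev <- abs(X - means[sid, , drop = FALSE])
  apply(rowsum(dev, sid), 1, max)
}

#' Pearson dispersion of a conditional fit
#'
#' Ratio of the Pearson chi-square statistic to the residual degrees of
#' freedom over informative strata:
#' \eqn{\phi = \sum (y_i - \hat\mu_i)^2/\hat\mu_i \; / \;
#' (n - S - p)}, where `S` is the number of informative strata and `p` the
#' number of exposure parameters. Values near 1 indicate Poisson variation;
#' larger values indicate overdispersion.
#'
#' @param fit An `hw_fit` object.
#' @return The dispersion estimate (a single number).
#' @export
estimate_dispersion <- function(fit) {
  stopifnot(inherits(fit, "hw_fit"))
  if (is.na(fit$dispersion)) {
    abort("Non-positive residual degrees of freedom: dispersion undefined.")
  }
  fit$dispersion
}

#' Convert a log-rate coefficient to a percent change
#'
#' Reporting transform for case-crossover coefficients: the percent change
#' in daily event counts per unit exposure is \eqn{(e^\beta - 1)\times 100},
#' with a Wald 95% interval
#' \eqn{((e^{\beta - 1.96\,se} - 1)\times 100,\; (e^{\beta + 1.96\,se} - 1)\times 100)}
#' and a two-sided normal p-value from \eqn{z = \beta / se}.
#'
#' @param beta Log-scale coefficient(s).
#' @param se_beta Standard error(s) on the log scale, positive.
#' @param label Optional label(s) carried through to the output.
#' @return A tibble with `label`, `beta`, `se_beta`, `percent_change`,
#'   `ci_low`, `ci_high`, `p_value`.
#' @examples
#' percent_change(log(1.0123), 0.001)
#' @export
percent_change <- function(beta, se_beta, label = NA_character_) {
  if (any(!is.finite(beta)) || any(!is.finite(se_beta))) {
    abort("`beta` and `se_beta` must be finite.")
  }
  if (any(se_beta <= 0)) abort("`se_beta` must be positive.")
  z <- qnorm(0.975)
  tibble(
    label = label,
    beta = beta,
    se_beta = se_beta,
    percent_change = (exp(beta) - 1) * 100,
    ci_low = (exp(beta - z * se_beta) - 1) * 100,
    ci_high = (exp(beta + z * se_beta) - 1) * 100,
    p_value = 2 * pnorm(-abs(beta / se_beta))
  )
}
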