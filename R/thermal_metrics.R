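# Per-pool thermal-variability metrics from daily temperature-logger series.
#
# The workflow: detrend the seasonal component of daily maximum temperature
# with a quadratic GLS whose residuals carry a Gaussian temporal-correlation
# structure, then summarise each pool with five climate metrics used as
# covariates downstream:
#   * mean daily mean temperature over the window,
#   * mean daily maximum in the hottest month (within-generation extreme),
#   * daily SD of detrended maxima (within-generation variation),
#   * predictability = range of the Gaussian variogram (days over which
#     daily maxima stay autocorrelated),
#   * seasonal range of daily maxima (among-generation variation).

#' Validate a per-pool daily temperature series
#'
#' A temperature series is a data frame with one row per day holding the
#' pool identifier, integer day-of-year, and daily maximum and mean water
#' temperature in degrees Celsius.
#'
#' @param series data frame with columns `pool_id`, `day`, `daily_max`,
#'   `daily_mean`.
#' @return the validated series (invisibly usable), with rows ordered by day.
#' @export
validate_temperature_series <- function(series) {
  req <- c("pool_id", "day", "daily_max", "daily_mean")
  miss <- setdiff(req, names(series))
  if (length(miss) > 0) {
    stop("temperature series missing column(s): ", paste(miss, collapse = ", "))
  }
  series <- series[order(series$day), , drop = FALSE]
  if (anyDuplicated(series$day)) {
    stop("temperature series for pool ", series$pool_id[1],
         " has duplicated day(s): ",
         paste(unique(series$day[duplicated(series$day)]), collapse = ", "))
  }
  temps <- c(series$daily_max, series$daily_mean)
  if (any(!is.finite(temps)) || any(temps < -10) || any(temps > 60)) {
    stop("temperatures must be finite and within [-10, 60] degrees C")
  }
  if (length(unique(series$pool_id)) != 1) {
    stop("a temperature series must belong to a single pool")
  }
  series
}

#' Fit a quadratic seasonal trend with Gaussian temporal correlation
#'
#' Fits, by joint maximum likelihood, a quadratic model of daily maximum
#' temperature on day-of-year with residual temporal correlation
#' `exp(-(h / range)^2)` between observations `h` days apart (the Gaussian
#' variogram model). The day covariate is centred and scaled internally for
#' conditioning; trend coefficients are reported on the original day-of-year
#' scale. The fit is multi-started over a grid of initial correlation ranges
#' and the highest-likelihood converged fit is kept.
#'
#' The residual SD is the sample SD of the detrended residuals, and the
#' variogram range is the number of days over which daily maxima remain
#' autocorrelated -- the "predictability" of the thermal environment.
#'
#' @param series a validated temperature series (see
#'   [validate_temperature_series()]).
#' @param nugget logical; estimate a nugget effect (default `TRUE`). The
#'   Gaussian correlation model without a nugget is numerically degenerate
#'   for smooth series (its correlation matrix is near-singular at ranges of
#'   a few days), which collapses the estimated range towards zero; the
#'   nugget absorbs measurement-scale noise and makes the range
#'   identifiable, standard practice in variogram modelling.
#' @param start_ranges numeric vector of initial range values (days) for the
#'   multi-start.
#' @return an object of class `gls_variogram_fit`: list with
#'   `trend_coefficients` (a, b, c of `a + b*day + c*day^2`), `residual_sd`,
#'   `variogram_range`, `sill`, `nugget`, `converged`, `log_likelihood`,
#'   `n_obs`, `missing_fraction`, and the residuals.
#' @export
fit_gls_quadratic <- function(series, nugget = TRUE,
                              start_ranges = c(1, 3, 5, 7, 14)) {
  series <- validate_temperature_series(series)
  n <- nrow(series)
  if (n < 30) stop("need at least 30 daily observations, got ", n)
  span <- diff(range(series$day))
  if (span < 30) stop("series must span at least 30 days, spans ", span)
  missing_fraction <- 1 - n / (span + 1)
  if (missing_fraction > 0.2) {
    warning("pool ", series$pool_id[1], ": more than 20% of days missing (",
            round(100 * missing_fraction), "%)")
  }

  # noiseless (or constant) series: the quadratic explains everything and the
  # correlation model is undefined; report exact trend and zero residual SD
  ols <- lm(daily_max ~ day + I(day^2), data = series)
  if (sd(resid(ols)) < 1e-8 * max(1, sd(series$daily_max))) {
    b <- coef(ols); b[is.na(b)] <- 0
    return(structure(list(
      pool_id = series$pool_id[1],
      trend_coefficients = c(a = unname(b[1]), b = unname(b[2]),
                             c = unname(b[3])),
      residual_sd = sd(resid(ols)), variogram_range = NA_real_,
      sill = 0, nugget = 0,
      converged = TRUE, log_likelihood = as.numeric(stats::logLik(ols)),
      n_obs = n, missing_fraction = missing_fraction,
      residuals = as.numeric(resid(ols)), series = series
    ), class = "gls_variogram_fit"))
  }

  day_c <- scale(series$day)
  dat <- data.frame(
    y = series$daily_max,
    d = as.numeric(day_c),
    day = series$day
  )
  ctr <- attr(day_c, "scaled:center")
  scl <- attr(day_c, "scaled:scale")

  fit_one <- function(r0) {
    init <- if (nugget) c(range = r0 / scl, nugget = 0.1) else c(range = r0 / scl)
    tryCatch(
      nlme::gls(
        y ~ d + I(d^2), data = dat,
        correlation = nlme::corGaus(value = init, form = ~ d, nugget = nugget),
        method = "ML",
        control = nlme::glsControl(opt = "optim", maxIter = 200, msMaxIter = 200)
      ),
      error = function(e) NULL
    )
  }
  fits <- lapply(start_ranges, fit_one)
  fits <- fits[!vapply(fits, is.null, logical(1))]

  if (length(fits) == 0) {
    # non-convergence from every start: flag, metrics unusable downstream
    return(structure(list(
      pool_id = series$pool_id[1],
      trend_coefficients = c(a = NA_real_, b = NA_real_, c = NA_real_),
      residual_sd = NA_real_, variogram_range = NA_real_,
      sill = NA_real_, nugget = NA_real_,
      converged = FALSE, log_likelihood = NA_real_,
      n_obs = n, missing_fraction = missing_fraction,
      residuals = rep(NA_real_, n), series = series
    ), class = "gls_variogram_fit"))
  }

  ll <- vapply(fits, function(f) as.numeric(stats::logLik(f)), numeric(1))
  best <- fits[[which.max(ll)]]

  cs <- coef(best$modelStruct$corStruct, unconstrained = FALSE)
  range_days <- unname(cs["range"]) * scl
  nug <- if (nugget) unname(cs["nugget"]) else 0
  res <- as.numeric(resid(best))
  res_sd <- sd(res)
  sill <- best$sigma^2

  # back-transform coefficients from the centred/scaled basis to day-of-year:
  # y = b0 + b1*z + b2*z^2, z = (day - ctr)/scl
  b <- coef(best)
  a_orig <- b[1] - b[2] * ctr / scl + b[3] * ctr^2 / scl^2
  b_orig <- b[2] / scl - 2 * b[3] * ctr / scl^2
  c_orig <- b[3] / scl^2

  structure(list(
    pool_id = series$pool_id[1],
    trend_coefficients = c(a = unname(a_orig), b = unname(b_orig),
                           c = unname(c_orig)),
    residual_sd = res_sd,
    variogram_range = range_days,
    sill = sill,
    nugget = nug * sill,
    converged = TRUE,
    log_likelihood = max(ll),
    n_obs = n,
    missing_fraction = missing_fraction,
    residuals = res,
    series = series
  ), class = "gls_variogram_fit")
}

#' @export
print.gls_variogram_fit <- function(x, ...) {
  cat("Quadratic GLS fit with Gaussian temporal correlation\n")
  cat("  pool:", as.character(x$pool_id), " n =", x$n_obs, "\n")
  if (!x$converged) {
    cat("  DID NOT CONVERGE -- metrics unusable\n")
    return(invisible(x))
  }
  cat(sprintf("  residual SD: %.3f degC   variogram range: %.2f days\n",
              x$residual_sd, x$variogram_range))
  cat(sprintf("  logLik: %.2f\n", x$log_likelihood))
  invisible(x)
}

#' Summarise one pool's climate from its series and detrending fit
#'
#' @param series validated temperature series for one pool.
#' @param fit the [fit_gls_quadratic()] result for the same series.
#' @param hottest_month integer month (default 8, August) whose mean daily
#'   maximum is reported; use `"empirical"` to pick the calendar month with
#'   the highest mean daily maximum.
#' @return one-row data frame with `pool_id`, `mean_daily_mean`,
#'   `hottest_month_mean_daily_max`, `daily_sd`, `predictability_days`,
#'   `seasonal_range`.
#' @export
summarize_pool <- function(series, fit, hottest_month = 8) {
  series <- validate_temperature_series(series)
  if (!isTRUE(fit$converged)) {
    stop("detrending fit for pool ", series$pool_id[1],
         " did not converge; climate metrics unusable")
  }
  month_of <- month_from_doy(series$day)
  if (identical(hottest_month, "empirical")) {
    mu <- tapply(series$daily_max, month_of, mean)
    hottest_month <- as.integer(names(mu)[which.max(mu)])
  }
  in_month <- month_of == hottest_month
  if (!any(in_month)) {
    stop("no observations in month ", hottest_month, " for pool ",
         series$pool_id[1])
  }
  data.frame(
    pool_id = series$pool_id[1],
    mean_daily_mean = mean(series$daily_mean),
    hottest_month_mean_daily_max = mean(series$daily_max[in_month]),
    daily_sd = fit$residual_sd,
    predictability_days = fit$variogram_range,
    seasonal_range = max(series$daily_max) - min(series$daily_max),
    stringsAsFactors = FALSE
  )
}

#' Climate metrics for a list of pool series
#'
#' Convenience wrapper: fits the detrending model and summarises every pool.
#' Pools whose fit fails to converge are dropped with a warning.
#'
#' @param series_list list of temperature series (one per pool), as returned
#'   by [read_temperature_csv()].
#' @inheritParams summarize_pool
#' @inheritParams fit_gls_quadratic
#' @return data frame with one row per converged pool.
#' @export
pool_climate_table <- function(series_list, hottest_month = 8, nugget = TRUE) {
  rows <- lapply(series_list, function(s) {
    fit <- fit_gls_quadratic(s, nugget = nugget)
    if (!fit$converged) {
      warning("pool ", s$pool_id[1], ": detrending did not converge; dropped")
      return(NULL)
    }
    summarize_pool(s, fit, hottest_month = hottest_month)
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

# month for a 1-based day-of-year in a non-leap year
month_from_doy <- function(doy) {
  ends <- cumsum(c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31))
  findInterval(doy - 1, c(0, ends[-12])) # 1..12
}
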