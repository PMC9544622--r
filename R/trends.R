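#' Theil-Sen slope of an annual series
#'
#' Median of all pairwise slopes `(y_j - y_i)/(t_j - t_i)`, `i < j`.
#' Missing values are removed pairwise.
#'
#' @param values numeric annual values.
#' @param years time vector (default `seq_along(values)`).
#' @return the Sen slope in units per year.
#' @export
sen_slope <- function(values, years = seq_along(values)) {
  ok <- is.finite(values) & is.finite(years)
  y <- values[ok]; t <- years[ok]
  n <- length(y)
  if (n < 3) stop("at least 3 non-missing values required")
  ij <- utils::combn(n, 2)
  stats::median((y[ij[2, ]] - y[ij[1, ]]) / (t[ij[2, ]] - t[ij[1, ]]))
}

#' Linear (OLS) trend with IAV diagnostics
#'
#' Ordinary least squares of `values` on `years`; the inter-annual
#' variability (IAV) is the standard deviation of the de-trended residuals
#' (denominator n-1). Sen's slope is reported alongside; its significance
#' is taken from the OLS slope t-test (two-sided), with `p < .1` labelled
#' "marginally significant" and `p < .05` significant.
#'
#' @param values numeric annual values.
#' @param years time vector (default `seq_along(values)`).
#' @return object of class `flux_trend`: `sen_slope`, `ols_slope`, `r2`,
#'   `p`, `n`, `mean`, `relative_slope` (% a-1 of the mean), `iav_sd`,
#'   `significance` and `residuals`.
#' @export
linear_trend <- function(values, years = seq_along(values)) {
  ok <- is.finite(values) & is.finite(years)
  y <- values[ok]; t <- years[ok]
  if (length(y) < 3) stop("at least 3 non-missing values required")
  if (stats::var(t) == 0) stop("constant time vector")
  fit <- stats::lm(y ~ t)
  sm <- summary(fit)
  sen <- sen_slope(y, t)
  p <- sm$coefficients[2, 4]
  structure(list(sen_slope = sen,
                 ols_slope = unname(stats::coef(fit)[2]),
                 r2 = sm$r.squared, p = p, n = length(y), mean = mean(y),
                 relative_slope = 100 * sen / mean(y),
                 iav_sd = stats::sd(stats::resid(fit)),
                 significance = if (p < 0.05) "p<.05"
                                else if (p < 0.1) "marginally significant"
                                else "ns",
                 residuals = unname(stats::resid(fit))),
            class = "flux_trend")
}

#' @export
print.flux_trend <- function(x, ...) {
  cat(sprintf(
    "Trend over %d years: Sen %.3g, OLS %.3g per year (%.2f%% a-1 of mean %.4g)\n",
    x$n, x$sen_slope, x$ols_slope, x$relative_slope, x$mean))
  cat(sprintf("  r2 = %.2f, p = %.3g (%s); IAV (de-trended SD) = %.3g\n",
              x$r2, x$p, x$significance, x$iav_sd))
  invisible(x)
}

#' De-trend an annual series
#'
#' Residuals from OLS on years; their mean is zero to machine precision.
#'
#' @inheritParams linear_trend
#' @return numeric residual vector (NA where input was missing).
#' @export
detrend <- function(values, years = seq_along(values)) {
  ok <- is.finite(values) & is.finite(years)
  if (sum(ok) < 3) stop("at least 3 non-missing values required")
  out <- rep(NA_real_, length(values))
  fit <- stats::lm(values[ok] ~ years[ok])
  out[ok] <- stats::resid(fit)
  out
}

#' Moving 31-day window annual means of a daily series
#'
#' For each calendar day, the 15 previous and 15 subsequent days are
#' selected (crossing year boundaries into adjacent years) and averaged per
#' year. A window mean is reported only when at least `min_days` of the 31
#' days are present.
#'
#' @param daily data.frame with columns `year`, `doy`, and `value`
#'   (chronological, one row per day).
#' @param width window width in days (odd, default 31).
#' @param min_days minimum days present per window (default 24).
#' @return matrix `[365 x n_years]` of window means, rownames the center
#'   day-of-year, colnames the years.
#' @export
moving_window_annual <- function(daily, width = 31, min_days = 24) {
  stopifnot(all(c("year", "doy", "value") %in% names(daily)))
  half <- width %/% 2
  x <- daily$value
  n <- length(x)
  ok <- !is.na(x)
  cs <- cumsum(ifelse(ok, x, 0)); cn <- cumsum(ok)
  win_mean <- function(i) {
    lo <- max(i - half, 1L); hi <- min(i + half, n)
    cnt <- cn[hi] - c(0, cn)[lo]
    if (hi - lo + 1L < width || cnt < min_days) return(NA_real_)
    (cs[hi] - c(0, cs)[lo]) / cnt
  }
  years <- sort(unique(daily$year))
  out <- matrix(NA_real_, nrow = 365, ncol = length(years),
                dimnames = list(1:365, years))
  for (yi in seq_along(years)) {
    rows <- which(daily$year == years[yi] & daily$doy <= 365)
    for (r in rows) out[daily$doy[r], yi] <- win_mean(r)
  }
  out
}

#' Partial correlation with controls
#'
#' Correlation between the residuals of `y` and `x` after OLS regression on
#' the control variables; with no controls this is the Pearson correlation.
#' The p-value comes from `t = rp sqrt((n - 2 - k)/(1 - rp^2))` (two-sided).
#'
#' @param y,x numeric vectors of the same length.
#' @param controls optional numeric matrix/data.frame of control variables.
#' @return named vector `c(rp, p, n)`; `rp` is `NA` when a residual series
#'   has zero variance.
#' @export
partial_correlation <- function(y, x, controls = NULL) {
  cm <- cbind(y = y, x = x, controls)
  ok <- stats::complete.cases(cm)
  cm <- cm[ok, , drop = FALSE]
  n <- nrow(cm)
  k <- ncol(cm) - 2L
  if (n < 4 + k) stop("too few complete cases")
  if (k > 0) {
    z <- cm[, -(1:2), drop = FALSE]
    ry <- stats::resid(stats::lm.fit(cbind(1, z), cm[, 1]))
    rx <- stats::resid(stats::lm.fit(cbind(1, z), cm[, 2]))
  } else {
    ry <- cm[, 1] - mean(cm[, 1]); rx <- cm[, 2] - mean(cm[, 2])
  }
  if (stats::sd(ry) == 0 || stats::sd(rx) == 0)
    return(c(rp = NA_real_, p = NA_real_, n = n))
  rp <- stats::cor(ry, rx)
  df <- n - 2L - k
  tval <- rp * sqrt(df / (1 - rp^2))
  c(rp = rp, p = 2 * stats::pt(-abs(tval), df), n = n)
}

#' Critical correlation magnitude at a given significance level
#'
#' `r* = t*/sqrt(t*^2 + df)` with `t*` the two-sided `alpha` quantile of
#' the t distribution and `df = n - 2 - k`.
#'
#' @param n sample size (years).
#' @param alpha two-sided significance level.
#' @param k_controls number of control variables.
#' @return the threshold |r| above which `p < alpha`.
#' @examples critical_r(17, 0.1) # ~0.41
#' @export
critical_r <- function(n, alpha = 0.05, k_controls = 0) {
  df <- n - 2 - k_controls
  if (df < 1) stop("n - 2 - k must be >= 1")
  tstar <- stats::qt(1 - alpha / 2, df)
  tstar / sqrt(tstar^2 + df)
}

#' Minimal detectable trend of a noisy annual series
#'
#' Inversion of the standard trend-detection sample-size formula:
#' `omega_min = 3.3 sigma_N sqrt((1 + phi)/(1 - phi)) / n^{3/2}`, the trend
#' magnitude detectable (p < .05) after `n_years` given noise SD `sigma_N`
#' and lag-1 autocorrelation `phi`.
#'
#' @param iav_sd de-trended noise standard deviation (`sigma_N`).
#' @param ar1_phi lag-1 autocorrelation of the noise, `|phi| < 1`.
#' @param n_years record length in years.
#' @return minimal detectable trend, units of `iav_sd` per year.
#' @export
detection_limit <- function(iav_sd, ar1_phi = 0, n_years = 17) {
  stopifnot(iav_sd >= 0, n_years >= 3)
  if (abs(ar1_phi) >= 1) stop("|phi| must be < 1")
  3.3 * iav_sd * sqrt((1 + ar1_phi) / (1 - ar1_phi)) / n_years^1.5
}

#' Lag-1 autocorrelation of de-trended annual residuals (floored at 0)
#'
#' @inheritParams linear_trend
#' @return numeric scalar in `[0, 1)`.
#' @export
ar1_of_residuals <- function(values, years = seq_along(values)) {
  r <- detrend(values, years)
  r <- r[is.finite(r)]
  max(stats::cor(r[-1], r[-length(r)]), 0)
}

#' Moving-window de-trended partial correlations of IAV drivers
#'
#' For each calendar day, the 31-day window means per year of the response
#' and each driver are de-trended (linear, within the window) and the
#' partial correlation between response and each driver is computed
#' controlling for the remaining drivers.
#'
#' @param resp_daily data.frame `year`, `doy`, `value` of the response.
#' @param driver_list named list of like-shaped data.frames (drivers).
#' @param width window width, days (default 31).
#' @param alpha recording threshold: correlations with `p < alpha` are
#'   flagged in the `significant` column (default 0.1); all values are
#'   retained.
#' @return data.frame `doy`, `driver`, `rp`, `p`, `n`, `significant`.
#' @export
iav_driver_correlation <- function(resp_daily, driver_list, width = 31,
                                   alpha = 0.1) {
  ym <- moving_window_annual(resp_daily, width)
  dm <- lapply(driver_list, moving_window_annual, width = width)
  yrs <- as.numeric(colnames(ym))
  out <- list()
  for (d in seq_len(nrow(ym))) {
    yv <- ym[d, ]
    if (sum(is.finite(yv)) < 5) next
    ydt <- tryCatch(detrend(yv, yrs), error = function(e) NULL)
    if (is.null(ydt)) next
    xdt <- lapply(dm, function(m) tryCatch(detrend(m[d, ], yrs),
                                           error = function(e) rep(NA_real_, length(yrs))))
    for (nm in names(dm)) {
      ctrl <- do.call(cbind, xdt[setdiff(names(dm), nm)])
      pc <- tryCatch(partial_correlation(ydt, xdt[[nm]], ctrl),
                     error = function(e) c(rp = NA_real_, p = NA_real_, n = NA_real_))
      out[[length(out) + 1L]] <- data.frame(
        doy = d, driver = nm, rp = pc[["rp"]], p = pc[["p"]], n = pc[["n"]],
        significant = is.finite(pc[["p"]]) && pc[["p"]] < alpha)
    }
  }
  do.call(rbind, out)
}
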