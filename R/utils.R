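## Internal constants and small helpers shared across modules.

# seconds per half-hourly flux averaging period
HALF_HOUR <- 1800
# 1 umol CO2 = 12.011 ugC; converts umol m-2 s-1 sums to gC m-2
UMOL_CO2_TO_GC <- 12.011e-6
# 1 mmol H2O = 18.015 mg = 18.015e-6 kg => mm of water per m2
MMOL_H2O_TO_MM <- 18.015e-6
# default site: SMEAR II / FI-Hyy, southern Finland
SITE_LAT <- 61.85
SITE_LON <- 24.28
SITE_TZ  <- 2          # local standard time UTC+2, no daylight saving
PATM_KPA <- 101.3
MISSING_SENTINEL <- -9999

#' Saturation vapor pressure of water
#'
#' Tetens form over liquid water.
#'
#' @param ta air temperature, degrees C.
#' @return saturation vapor pressure, kPa.
#' @keywords internal
esat_kpa <- function(ta) 0.6108 * exp(17.27 * ta / (ta + 237.3))

## Run a block with a temporary RNG state derived from `seed`, restoring the
## caller's stream afterwards so generators are pure functions of their seed.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

## AR(1) series of length n, marginal sd `sd`, lag-1 coefficient `phi`.
ar1 <- function(n, phi, sd) {
  if (n == 0L) return(numeric(0))
  if (sd <= 0) return(rep(0, n))
  innov_sd <- sd * sqrt(1 - phi^2)
  as.numeric(stats::filter(stats::rnorm(n, 0, innov_sd), phi,
                           method = "recursive",
                           init = stats::rnorm(1, 0, sd)))
}

## Exponential moving average with smoothing factor alpha in (0,1].
ema <- function(x, alpha) {
  as.numeric(stats::filter(alpha * x, 1 - alpha, method = "recursive",
                           init = x[1]))
}

## Centered rolling mean with window `width` (odd); NA at the edges unless
## `min_obs` values are present.
roll_mean <- function(x, width, min_obs = width) {
  n <- length(x)
  half <- width %/% 2
  xs <- c(rep(NA_real_, half), x, rep(NA_real_, half))
  ok <- !is.na(xs)
  cs <- cumsum(ifelse(ok, xs, 0))
  cn <- cumsum(ok)
  i <- seq_len(n)
  tot <- cs[i + 2 * half] - c(0, cs)[i]
  cnt <- cn[i + 2 * half] - c(0, cn)[i]
  out <- ifelse(cnt >= min_obs, tot / cnt, NA_real_)
  out
}

## day-of-year (1-based) and decimal hour (local standard time) of a POSIXct
time_parts <- function(timestamp) {
  lt <- as.POSIXlt(timestamp)
  list(year = lt$year + 1900L,
       doy = lt$yday + 1L,
       hour = lt$hour + lt$min / 60 + lt$sec / 3600)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
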