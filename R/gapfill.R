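#' Fill flux gaps by marginal distribution sampling
#'
#' A condensed re-implementation of the look-up-table gap filling that is
#' standard for half-hourly eddy-covariance data. Each missing half-hour is
#' replaced by the mean of observed values measured under similar
#' meteorological conditions (|dRg| <= 50 W m-2, |dTa| <= 2.5 C,
#' |dD| <= 0.5 kPa) within an expanding time window (+/-7, 14, ... days).
#' If no match exists, the radiation condition alone is tried, and finally
#' the mean diurnal course (same time of day +/-1 h) in windows expanding to
#' +/-60 days; such fills are flagged low-quality.
#'
#' @param series a `flux_series` with `gap_flag` set (`"gap"` where missing).
#' @param forcing the complete `forcing_series` on the same grid.
#' @param columns flux columns to fill (default `c("NEP", "ET")`).
#' @return the series with no missing values in `columns`, `gap_flag` set to
#'   `"filled"` where a fill happened, and a `fill_quality` column: window
#'   half-width in days (negative when met-similarity had to be dropped).
#' @export
fill_gaps_mds <- function(series, forcing, columns = c("NEP", "ET")) {
  stopifnot(nrow(series) == nrow(forcing))
  n <- nrow(series)
  gaps <- which(series$gap_flag == "gap")
  series$fill_quality <- NA_real_
  if (length(gaps) == 0L) return(series)

  rg <- forcing$Rg; ta <- forcing$Ta; d <- forcing$D
  per_day <- 48L
  obs <- series$gap_flag == "observed"

  lookup <- function(i, col_vals, col_obs) {
    # stage 1: full met similarity, expanding +/-7, +/-14 d
    for (w in c(7L, 14L)) {
      lo <- max(1L, i - w * per_day); hi <- min(n, i + w * per_day)
      j <- lo:hi
      m <- j[col_obs[j] &
               abs(rg[j] - rg[i]) <= 50 &
               abs(ta[j] - ta[i]) <= 2.5 &
               abs(d[j] - d[i]) <= 0.5]
      if (length(m) >= 2L) return(c(mean(col_vals[m]), w))
    }
    # stage 2: radiation similarity only
    for (w in c(7L, 14L, 28L)) {
      lo <- max(1L, i - w * per_day); hi <- min(n, i + w * per_day)
      j <- lo:hi
      m <- j[col_obs[j] & abs(rg[j] - rg[i]) <= 50]
      if (length(m) >= 2L) return(c(mean(col_vals[m]), -w))
    }
    # stage 3: mean diurnal course, same time of day +/-1 h
    for (w in c(7L, 14L, 28L, 60L)) {
      off <- as.vector(outer(-2:2, per_day * (-w:w), `+`))
      j <- i + off
      j <- j[j >= 1L & j <= n]
      m <- j[col_obs[j]]
      if (length(m) >= 2L) return(c(mean(col_vals[m]), -w))
    }
    c(mean(col_vals[col_obs], na.rm = TRUE), -Inf)
  }

  for (col in columns) {
    vals <- series[[col]]
    for (i in gaps) {
      res <- lookup(i, vals, obs)
      series[[col]][i] <- res[1]
      series$fill_quality[i] <- res[2]
    }
  }
  series$gap_flag[gaps] <- "filled"
  series
}
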