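#' PAR-class (binned) light-response analysis
#'
#' Standardizes peak-season half-hours for environmental conditions by
#' clustering them into PAR classes, averaging per year and class, fitting
#' a rectangular-hyperbola light response to the binned averages, and
#' (optionally downstream) evaluating trends separately per class. Intended
#' for the phenologically stationary mid-summer window (default July 1 -
#' August 10), dry-canopy half-hours and sufficiently moist soils.
#'
#' @param series partitioned `flux_series` (column `GPP`).
#' @param forcing matching `forcing_series`.
#' @param bins PAR bin edges, umol m-2 s-1 (default 0 to 1800 by 200).
#' @param period `c("MM-DD","MM-DD")` inclusive window (default
#'   `c("07-01","08-10")`).
#' @param dry logical mask of dry-canopy half-hours (default: 24-h lookback
#'   on `forcing$P`).
#' @param rew_min minimum relative extractable water (default 0.3).
#' @return list with `bin_means` (data.frame year x bin: mean PAR, GPP, n)
#'   and `fits` (per-year `c(alpha, pmax)` of
#'   `GPP = pmax alpha PAR / (pmax + alpha PAR)`).
#' @export
light_response_binned <- function(series, forcing,
                                  bins = seq(0, 1800, by = 200),
                                  period = c("07-01", "08-10"),
                                  dry = NULL, rew_min = 0.3) {
  stopifnot(nrow(series) == nrow(forcing))
  if (is.null(dry)) dry <- dry_canopy_mask(forcing$P, 24)
  md <- sprintf("%02d-%02d", as.POSIXlt(forcing$timestamp)$mon + 1,
                as.POSIXlt(forcing$timestamp)$mday)
  sel <- md >= period[1] & md <= period[2] & dry &
    forcing$Rew >= rew_min & forcing$PAR > 0 & !is.na(series$GPP)
  bin <- cut(forcing$PAR, bins, right = TRUE, include.lowest = FALSE)
  sel <- sel & !is.na(bin)
  key <- interaction(forcing$year[sel], bin[sel], drop = FALSE)
  grid <- expand.grid(bin = levels(bin),
                      year = sort(unique(forcing$year[sel])))
  key_all <- interaction(grid$year, grid$bin)
  m_par <- tapply(forcing$PAR[sel], key, mean)
  m_gpp <- tapply(series$GPP[sel], key, mean)
  n_obs <- tapply(rep(1, sum(sel)), key, length)
  bin_means <- data.frame(year = grid$year, bin = as.character(grid$bin),
                          PAR = as.numeric(m_par[as.character(key_all)]),
                          GPP = as.numeric(m_gpp[as.character(key_all)]),
                          n = as.numeric(n_obs[as.character(key_all)]))
  bin_means$n[is.na(bin_means$n)] <- 0

  fits <- lapply(split(bin_means, bin_means$year), function(df) {
    df <- df[df$n > 0 & is.finite(df$GPP), ]
    if (nrow(df) < 3) return(c(alpha = NA_real_, pmax = NA_real_))
    fit_light_response(df$PAR, df$GPP)
  })
  list(bin_means = bin_means, fits = do.call(rbind, fits))
}

#' Fit a rectangular-hyperbola light response
#'
#' `GPP = Pmax alpha PAR / (Pmax + alpha PAR)`.
#'
#' @param par,gpp paired PAR (umol m-2 s-1) and GPP values.
#' @return named vector `c(alpha, pmax)`.
#' @export
fit_light_response <- function(par, gpp) {
  fit <- tryCatch(
    minpack.lm::nlsLM(gpp ~ pm * a * par / (pm + a * par),
                      start = list(a = 0.03, pm = max(gpp) * 1.2),
                      lower = c(1e-6, 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(c(alpha = NA_real_, pmax = NA_real_))
  cf <- stats::coef(fit)
  c(alpha = unname(cf[["a"]]), pmax = unname(cf[["pm"]]))
}
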