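#' Big-leaf surface conductance for CO2
#'
#' `Gs = ET / (1.6 D/Patm)`: inversion of the big-leaf transpiration
#' relation, treating all of ET as stomatal. Masked (NA) below the VPD
#' threshold where the inversion is numerically unstable.
#'
#' @param et evapotranspiration, mol H2O m-2 s-1.
#' @param d vapor pressure deficit, kPa.
#' @param patm ambient pressure, kPa.
#' @param d_min mask threshold for `d`, kPa (default 0.05).
#' @return surface conductance for CO2, mol m-2 s-1 (`NA` where masked).
#' @export
surface_conductance <- function(et, d, patm = PATM_KPA, d_min = 0.05) {
  out <- et / (1.6 * d / patm)
  out[!is.finite(out) | d <= d_min | et < 0] <- NA_real_
  out
}

#' Ecosystem Ci/Ca, intrinsic and plain water-use efficiency, light-use
#' efficiency
#'
#' `CiCa = 1 - GPP/(Gs ca)`; `IWUE = GPP/Gs = ca (1 - CiCa)` (the identity
#' holds to machine precision); `WUE = GPP/ET` in mmol CO2 per mol H2O when
#' GPP is in umol and ET in mmol; `LUE = GPP/PAR` in mmol mol-1. All ratios
#' should be formed from daytime period sums, not means of ratios.
#'
#' @param gpp gross primary productivity, umol m-2 s-1 (or a period sum).
#' @param gs surface conductance, mol m-2 s-1.
#' @param ca ambient CO2, ppm.
#' @param et evapotranspiration, mmol m-2 s-1 (or a matching sum).
#' @param par incident PAR, umol m-2 s-1 (or a matching sum).
#' @return numeric vector; nonpositive denominators give `NA`.
#' @export
ecosystem_ci_ca <- function(gpp, gs, ca) {
  out <- 1 - gpp / (gs * ca)
  out[!is.finite(out) | gs <= 0 | ca <= 0] <- NA_real_
  out
}

#' @rdname ecosystem_ci_ca
#' @export
iwue <- function(gpp, gs) {
  out <- gpp / gs
  out[!is.finite(out) | gs <= 0] <- NA_real_
  out
}

#' @rdname ecosystem_ci_ca
#' @export
wue <- function(gpp, et) {
  out <- gpp / et
  out[!is.finite(out) | et <= 0] <- NA_real_
  out
}

#' @rdname ecosystem_ci_ca
#' @export
lue <- function(gpp, par) {
  out <- 1000 * gpp / par
  out[!is.finite(out) | par <= 0] <- NA_real_
  out
}

#' Dry-canopy mask
#'
#' A half-hour is dry iff no rain fell during the preceding
#' `lookback_hours` hours (default 12; 24 is the stricter convention used
#' for light-response analyses). Steps whose lookback window extends before
#' the record start are treated wet (unknown).
#'
#' @param p precipitation series, mm per half-hour, complete grid.
#' @param lookback_hours lookback length in hours; 0 tests only the current
#'   half-hour.
#' @return logical vector, `TRUE` where the canopy is dry.
#' @export
dry_canopy_mask <- function(p, lookback_hours = 12) {
  if (anyNA(p)) stop("precipitation series must be complete")
  k <- as.integer(round(lookback_hours * 2))
  n <- length(p)
  cs <- c(0, cumsum(p))
  i <- seq_len(n)
  # sum over (i-k) .. i inclusive of the current step
  lo <- pmax(i - k, 1L)
  tot <- cs[i + 1L] - cs[lo]
  # incomplete lookback at the record head counts as unknown -> wet
  (tot == 0) & (i - k >= 1L)
}

#' Daily aggregation helper
#'
#' @param series `flux_series` (uses `NEP`).
#' @param forcing matching `forcing_series`.
#' @return data.frame with `year`, `doy`, daily `NEP` (gC m-2 d-1) and
#'   daily mean `Ta`.
#' @export
daily_summary <- function(series, forcing) {
  key <- paste(forcing$year, sprintf("%03d", forcing$doy))
  u <- which(!duplicated(key))
  ord <- match(key[u], sort(unique(key)))
  nep_d <- as.numeric(tapply(series$NEP * HALF_HOUR * UMOL_CO2_TO_GC,
                             key, sum))[ord]
  ta_d <- as.numeric(tapply(forcing$Ta, key, mean))[ord]
  data.frame(year = forcing$year[u], doy = forcing$doy[u],
             NEP = nep_d, Ta = ta_d)
}
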