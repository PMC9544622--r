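#' Carbon uptake period from daily NEP
#'
#' Start of carbon uptake (SCU) is the first day in the first half-year
#' after which the 7-day smoothed daily NEP stays positive for at least
#' `persist` consecutive days; end of uptake (ECU) is the last day of the
#' last such spell. Both are undefined (NA) when daily NEP never sustains
#' positivity.
#'
#' @param nep_daily daily NEP for one year, gC m-2 d-1, complete.
#' @param smooth smoothing window, days (odd, default 7).
#' @param persist required persistence, days (default 5).
#' @return named numeric vector `c(SCU, ECU, CUP)` in day-of-year units.
#' @export
detect_cup <- function(nep_daily, smooth = 7, persist = 5) {
  n <- length(nep_daily)
  sm <- roll_mean(nep_daily, smooth, min_obs = (smooth + 1) %/% 2)
  pos <- !is.na(sm) & sm > 0
  r <- rle(pos)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= persist
  if (!any(keep)) return(c(SCU = NA_real_, ECU = NA_real_, CUP = NA_real_))
  s_cand <- starts[keep & starts <= n / 2]
  scu <- if (length(s_cand)) s_cand[1] else starts[keep][1]
  ecu <- ends[keep][sum(keep)]
  c(SCU = scu, ECU = ecu, CUP = ecu - scu)
}

#' Thermal growing season from daily mean air temperature
#'
#' Start = first day of the first `persist`-day spell with daily mean Ta
#' above `threshold` that begins after the last spring `persist`-day spell
#' below the threshold; end = last day of the last above-threshold spell.
#'
#' @param ta_daily daily mean air temperature for one year, C, complete.
#' @param threshold temperature threshold, C (default +5, the common Nordic
#'   convention).
#' @param persist spell length, days (default 5).
#' @return named numeric vector `c(GS_start, GS_end, GS_length)` (NA when
#'   the criterion is never met).
#' @export
thermal_growing_season <- function(ta_daily, threshold = 5, persist = 5) {
  n <- length(ta_daily)
  above <- ta_daily > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  long <- r$lengths >= persist
  a_starts <- starts[r$values & long]; a_ends <- ends[r$values & long]
  b_ends <- ends[!r$values & long]
  if (length(a_starts) == 0L)
    return(c(GS_start = NA_real_, GS_end = NA_real_, GS_length = NA_real_))
  # last cold spell ending in the first half-year
  spring_cold <- b_ends[b_ends <= n / 2]
  gate <- if (length(spring_cold)) max(spring_cold) else 0L
  cand <- a_starts[a_starts > gate]
  gs_start <- if (length(cand)) cand[1] else a_starts[1]
  gs_end <- a_ends[length(a_ends)]
  c(GS_start = gs_start, GS_end = gs_end, GS_length = gs_end - gs_start)
}
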