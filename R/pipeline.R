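#' Trend table for a set of annual series
#'
#' Convenience wrapper producing the standard trend summary (mean, Sen
#' slope, OLS slope, r2, p, de-trended IAV) for each column of an annual
#' data.frame, e.g. the packaged site record ([fihyy_annual()]) or
#' [aggregate_fluxes()] output.
#'
#' @param annual data.frame with a `year` column and numeric series.
#' @param columns columns to analyse (default: all numeric except `year`).
#' @return data.frame, one row per series.
#' @export
trend_table <- function(annual, columns = NULL) {
  if (is.null(columns))
    columns <- setdiff(names(annual)[vapply(annual, is.numeric, logical(1))],
                       "year")
  do.call(rbind, lapply(columns, function(v) {
    tr <- linear_trend(annual[[v]], annual$year)
    data.frame(series = v, mean = tr$mean, sen = tr$sen_slope,
               ols = tr$ols_slope, r2 = tr$r2, p = tr$p,
               iav_sd = tr$iav_sd, significance = tr$significance)
  }))
}

#' End-to-end synthetic pipeline
#'
#' Generates the synthetic record, injects gaps, gap-fills, partitions by
#' the nighttime approach and aggregates — the full measurement-analysis
#' chain on data with known truth.
#'
#' @param truth a [truth_params()].
#' @param years calendar years.
#' @param seed integer seed driving every random stage.
#' @param temp_source partitioning temperature, `"Ts"` or `"Ta"`.
#' @return list: `forcing`, `fluxes` (partitioned), `annual`
#'   (annual summaries), `annual_truth` (gap-free truth accumulation).
#' @export
run_pipeline <- function(truth = truth_params(), years = 2001:2017,
                         seed = 1L, temp_source = "Ts") {
  forcing <- generate_forcing(truth, years, seed)
  obs <- generate_observed_fluxes(forcing, truth, seed + 1L)
  truth_series <- obs
  gapped <- inject_gaps(obs, truth, seed + 2L)
  filled <- fill_gaps_mds(gapped, forcing)
  part <- partition_nighttime(filled, forcing, temp_source)
  annual <- aggregate_fluxes(part, forcing, "annual")
  truth_annual <- data.frame(
    year = sort(unique(forcing$year)),
    GPP = as.numeric(tapply(truth_series$GPP_truth * HALF_HOUR *
                              UMOL_CO2_TO_GC, forcing$year, sum)),
    Re = as.numeric(tapply(truth_series$Re_truth * HALF_HOUR *
                             UMOL_CO2_TO_GC, forcing$year, sum)),
    NEP = as.numeric(tapply(truth_series$NEP_truth * HALF_HOUR *
                              UMOL_CO2_TO_GC, forcing$year, sum)),
    ET = as.numeric(tapply(truth_series$ET_truth * HALF_HOUR *
                             MMOL_H2O_TO_MM, forcing$year, sum)))
  list(forcing = forcing, fluxes = part, annual = annual,
       annual_truth = truth_annual)
}
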