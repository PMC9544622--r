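#' Write a half-hourly record to FluxNet-style CSV
#'
#' Column dialect: ISO-8601 `TIMESTAMP_START`, variables `PAR`,
#' `PAR_DIF_FRAC`, `RG`, `TA`, `VPD`, `P`, `CA`, `TS_1`, `REW`, `WS`,
#' `PA`, `NEE` (micrometeorological sign, `NEE = -NEP`), `ET`, and
#' partitioned columns `GPP_TS`/`GPP_TA`/`RECO_TS`/`RECO_TA` when present.
#' Missing values are written as -9999. The writer/reader pair round-trips
#' losslessly.
#'
#' @param forcing a `forcing_series`.
#' @param path output file path.
#' @param fluxes optional `flux_series` on the same grid (adds NEE, ET and
#'   any partitioned columns).
#' @return `path`, invisibly.
#' @export
write_fluxnet_csv <- function(forcing, path, fluxes = NULL) {
  df <- data.frame(
    TIMESTAMP_START = format(forcing$timestamp, "%Y-%m-%dT%H:%M:%S"),
    PAR = forcing$PAR, PAR_DIF_FRAC = forcing$fd, RG = forcing$Rg,
    TA = forcing$Ta, VPD = forcing$D, P = forcing$P, CA = forcing$ca,
    TS_1 = forcing$Ts, REW = forcing$Rew, WS = forcing$U, PA = forcing$Patm)
  if (!is.null(fluxes)) {
    stopifnot(nrow(fluxes) == nrow(forcing))
    df$NEE <- -fluxes$NEP
    df$ET <- fluxes$ET
    df$QC_FLAG <- fluxes$gap_flag
    variant <- attr(fluxes, "variant")
    if (!is.null(fluxes$GPP) && !is.null(variant)) {
      df[[paste0("GPP_", toupper(variant))]] <- fluxes$GPP
      df[[paste0("RECO_", toupper(variant))]] <- fluxes$Re
    }
  }
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x)
    ifelse(is.na(x), MISSING_SENTINEL, x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a FluxNet-style half-hourly CSV
#'
#' Inverse of [write_fluxnet_csv()]: restores the -9999 sentinel to `NA`,
#' the micrometeorological `NEE` to `NEP = -NEE`, and recomputes the solar
#' zenith angle if needed.
#'
#' @param path CSV file path.
#' @param latitude,longitude site coordinates for the zenith computation.
#' @return list with elements `forcing` (`forcing_series`) and, when flux
#'   columns are present, `fluxes` (`flux_series`).
#' @export
read_fluxnet_csv <- function(path, latitude = SITE_LAT,
                             longitude = SITE_LON) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  ts <- as.POSIXct(df$TIMESTAMP_START, format = "%Y-%m-%dT%H:%M:%S",
                   tz = "Etc/GMT-2")
  if (anyNA(ts) || is.unsorted(as.numeric(ts), strictly = TRUE))
    stop("non-monotone or malformed TIMESTAMP_START")
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x)
    ifelse(x == MISSING_SENTINEL, NA_real_, x))
  tp <- time_parts(ts)
  forcing <- data.frame(timestamp = ts,
                        zenith = solar_position(ts, latitude, longitude),
                        PAR = df$PAR, fd = df$PAR_DIF_FRAC, Rg = df$RG,
                        Ta = df$TA, D = df$VPD, P = df$P, ca = df$CA,
                        Ts = df$TS_1, Rew = df$REW, WS = df$WS,
                        U = df$WS, Patm = df$PA,
                        year = tp$year, doy = tp$doy)
  class(forcing) <- c("forcing_series", "data.frame")
  out <- list(forcing = forcing)
  if (!is.null(df$NEE)) {
    fluxes <- data.frame(timestamp = ts, NEP = -df$NEE, ET = df$ET,
                         gap_flag = df$QC_FLAG %||%
                           ifelse(is.na(df$NEE), "gap", "observed"),
                         stringsAsFactors = FALSE)
    for (v in grep("^(GPP|RECO)_", names(df), value = TRUE))
      fluxes[[sub("RECO.*", "Re", sub("GPP.*", "GPP", v))]] <- df[[v]]
    class(fluxes) <- c("flux_series", "data.frame")
    out$fluxes <- fluxes
  }
  out
}

#' Published annual summary record of the FI-Hyy boreal pine site
#'
#' Loads the packaged plain-text table of annual and May-September values
#' (NEE, GPP and Re under soil- and air-temperature partitioning variants,
#' ET, met drivers, phenology dates and gap statistics) for 2001-2017,
#' usable as worked-example input to the trend statistics.
#'
#' @return data.frame with one row per year 2001-2017.
#' @export
fihyy_annual <- function() {
  path <- system.file("extdata", "fihyy_annual_2001_2017.csv",
                      package = "borealflux", mustWork = TRUE)
  utils::read.csv(path, check.names = FALSE)
}
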