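#' Solar zenith angle
#'
#' Solar position from the Astronomical Almanac low-precision algorithm
#' (Michalsky): solar declination and right ascension from the ecliptic
#' coordinates at the Julian epoch, the equation of time from the
#' longitude/right-ascension difference, accuracy of order 0.01 degrees.
#' Timestamps are interpreted as local standard time in the fixed zone
#' `tz_offset` (hours east of UTC, no daylight saving); the hour-angle
#' correction accounts for the offset between the site longitude and the
#' zone meridian.
#'
#' @param timestamp POSIXct vector, or anything `as.POSIXct` accepts.
#' @param latitude,longitude site coordinates in decimal degrees
#'   (defaults: a boreal Scots pine site at 61.85 N, 24.28 E).
#' @param tz_offset hours east of UTC of the local standard time (default 2).
#' @return numeric vector of solar zenith angles in degrees, in `[0, 180]`.
#'   Values >= 90 mean the sun is at or below the horizon.
#' @examples
#' solar_position(as.POSIXct("2008-06-21 12:30", tz = "Etc/GMT-2"))
#' @export
solar_position <- function(timestamp, latitude = SITE_LAT,
                           longitude = SITE_LON, tz_offset = SITE_TZ) {
  ts <- tryCatch(as.POSIXct(timestamp, tz = "Etc/GMT-2"),
                 error = function(e) stop("malformed timestamp"))
  if (any(is.na(ts))) stop("malformed timestamp")
  # days since J2000.0 (2000-01-01 12:00 UTC)
  n <- (as.numeric(ts) - 946728000) / 86400
  deg <- pi / 180
  L <- (280.460 + 0.9856474 * n) %% 360
  g <- ((357.528 + 0.9856003 * n) %% 360) * deg
  lambda <- (L + 1.915 * sin(g) + 0.020 * sin(2 * g)) * deg
  eps <- (23.439 - 0.0000004 * n) * deg
  decl <- asin(sin(eps) * sin(lambda))
  ra <- atan2(cos(eps) * sin(lambda), cos(lambda)) / deg
  eqtime <- 4 * (((L - ra + 180) %% 360) - 180)   # minutes
  tp <- time_parts(ts)
  tst <- tp$hour * 60 + eqtime + 4 * longitude - 60 * tz_offset
  ha <- (tst / 4 - 180) * deg
  lat <- latitude * deg
  cosz <- sin(lat) * sin(decl) + cos(lat) * cos(decl) * cos(ha)
  acos(pmin(pmax(cosz, -1), 1)) * 180 / pi
}

#' Half-hourly timestamp grid for complete calendar years
#'
#' @param years integer vector of calendar years.
#' @return POSIXct vector of period-start times (local standard time, UTC+2),
#'   strictly increasing on a complete 30-min grid.
#' @export
halfhour_grid <- function(years) {
  years <- sort(unique(as.integer(years)))
  if (length(years) == 0L) stop("at least one calendar year required")
  start <- as.POSIXct(sprintf("%d-01-01 00:00:00", min(years)), tz = "Etc/GMT-2")
  end <- as.POSIXct(sprintf("%d-01-01 00:00:00", max(years) + 1L), tz = "Etc/GMT-2")
  seq(start, end - 1, by = HALF_HOUR)
}
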