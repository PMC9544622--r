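#' Ground-truth parameters for the synthetic boreal record
#'
#' Bundles every knob of the synthetic-data generator: injected trends,
#' the light-response parameters of the data-generating GPP model, the
#' Lloyd-Taylor respiration truth, noise levels and the gap process. The
#' defaults emulate the 2001-2017 half-hourly record of a managed Scots
#' pine stand at 61.85 N: mean annual air temperature near +4 C,
#' precipitation near 711 mm, ambient CO2 rising 2.3 ppm a-1 from
#' 374.7 ppm, annual GPP near 1150 gC m-2, respiration near 900 gC m-2
#' and ET near 350 mm, with ~34% of NEP half-hours missing in clustered
#' gaps.
#'
#' @param ca0 ambient CO2 in the first year, ppm.
#' @param ca_trend linear trend of annual-mean CO2, ppm a-1.
#' @param lai0 one-sided leaf-area index in the first year, m2 m-2.
#' @param lai_trend relative LAI growth, fraction a-1 (e.g. 0.011 = 1.1% a-1).
#' @param gpp_trend injected relative trend of the truth GPP, fraction a-1.
#' @param alpha_q apparent quantum yield of the truth light response,
#'   umol CO2 per umol photons.
#' @param pmax light-saturated uptake of the truth light response,
#'   umol m-2 s-1.
#' @param rref truth base respiration at 15 C, umol m-2 s-1.
#' @param e0 truth Lloyd-Taylor temperature sensitivity, K.
#' @param noise_add additive flux noise SD, umol m-2 s-1 (and mmol for ET).
#' @param noise_prop flux-proportional noise SD, fraction of |flux|.
#' @param gap_fraction target missing fraction of NEP records, in `[0, 1)`.
#' @param gap_run mean gap run length, half-hours.
#' @param met_year_sd extra year-to-year temperature offset SD, C
#'   (set 0 together with the noise SDs for a cyclostationary record).
#' @param weather_sd daily synoptic temperature anomaly SD, C.
#' @param kt_sd daily clearness-index anomaly SD.
#' @param latitude,longitude site coordinates, decimal degrees.
#' @return object of class `truth_params` (a list).
#' @export
truth_params <- function(ca0 = 374.7, ca_trend = 2.3,
                         lai0 = 3.5, lai_trend = 0.011,
                         gpp_trend = 0.006,
                         alpha_q = 0.06, pmax = 20,
                         rref = 4.4, e0 = 230,
                         noise_add = 0.7, noise_prop = 0.10,
                         gap_fraction = 0.336, gap_run = 6,
                         met_year_sd = 0.35, weather_sd = 2.8,
                         kt_sd = 0.16,
                         latitude = SITE_LAT, longitude = SITE_LON) {
  stopifnot(gap_fraction >= 0, gap_fraction < 1, gap_run >= 1,
            alpha_q >= 0, pmax >= 0, rref >= 0, e0 >= 0,
            noise_add >= 0, noise_prop >= 0)
  structure(list(ca0 = ca0, ca_trend = ca_trend, lai0 = lai0,
                 lai_trend = lai_trend, gpp_trend = gpp_trend,
                 alpha_q = alpha_q, pmax = pmax, rref = rref, e0 = e0,
                 noise_add = noise_add, noise_prop = noise_prop,
                 gap_fraction = gap_fraction, gap_run = gap_run,
                 met_year_sd = met_year_sd, weather_sd = weather_sd,
                 kt_sd = kt_sd, latitude = latitude, longitude = longitude),
            class = "truth_params")
}

#' Annual leaf-area index series implied by the truth parameters
#'
#' @param truth a [truth_params()] object.
#' @param years integer vector of calendar years.
#' @return data.frame with `year` and `lai` (m2 m-2), linear relative growth
#'   `lai_trend` per year on the first-year value.
#' @export
annual_lai <- function(truth, years) {
  years <- sort(unique(as.integer(years)))
  data.frame(year = years,
             lai = truth$lai0 * (1 + truth$lai_trend * (years - years[1])))
}

#' Generate synthetic half-hourly meteorological forcing
#'
#' Harmonic seasonal and diurnal skeletons with AR(1) weather noise at the
#' daily scale plus per-year offsets; a marked two-state rain process (wet
#' half-hours force the diffuse fraction to 1 and cap vapor pressure
#' deficit); clearness-index-driven PAR with a logistic diffuse fraction;
#' soil temperature as a damped, snow-floored trace of air temperature; and
#' a simple soil-water bucket for relative extractable water.
#'
#' @param truth a [truth_params()] object.
#' @param years integer vector of complete calendar years to generate.
#' @param seed integer seed; identical seeds give bitwise-identical output.
#' @return data.frame (`forcing_series`): `timestamp`, `zenith` (deg),
#'   `PAR` (umol m-2 s-1), `fd` (diffuse fraction), `Rg` (W m-2), `Ta` (C),
#'   `D` (kPa), `P` (mm per half-hour), `ca` (ppm), `Ts` (C), `Rew` (-),
#'   `U` (m s-1), `Patm` (kPa), `year`, `doy`.
#' @export
generate_forcing <- function(truth = truth_params(), years = 2001:2017,
                             seed = 1L) {
  years <- sort(unique(as.integer(years)))
  if (length(years) == 0L) stop("zero-length year range")
  years <- seq(min(years), max(years))   # grid is contiguous
  with_seed(seed, {
    ts <- halfhour_grid(years)
    n <- length(ts)
    tp <- time_parts(ts)
    year <- tp$year; doy <- tp$doy; hour <- tp$hour
    dy <- year - years[1]
    zen <- solar_position(ts, truth$latitude, truth$longitude)
    cosz <- pmax(cos(zen * pi / 180), 0)

    day_id <- cumsum(c(1L, diff(doy) != 0 | diff(year) != 0))
    nd <- max(day_id)
    yr_of_day <- year[!duplicated(day_id)]
    yr_idx <- match(year, years)

    # a fully deterministic (cyclostationary) record when every noise SD is 0
    stoch <- truth$weather_sd > 0 || truth$kt_sd > 0 || truth$met_year_sd > 0

    # temperature: seasonal harmonic peaking late July + diurnal term tied to
    # solar elevation anomaly + daily AR(1) synoptics + yearly offset
    ta_season <- 4.0 + 11.5 * cos(2 * pi * (doy - 205) / 365.25)
    ta_anom_d <- ar1(nd, 0.80, truth$weather_sd)[day_id]
    ta_year <- stats::rnorm(length(years), 0, truth$met_year_sd)[yr_idx]
    cosz_daily <- ave(cosz, day_id)
    ta <- ta_season + 3.0 * (cosz - cosz_daily) + ta_anom_d + ta_year

    if (stoch) {
      # rain: two-state Markov chain of wet spells, exponential depths
      p01 <- 0.018; p10 <- 0.2
      u <- stats::runif(n)
      wet <- logical(n); state <- FALSE
      for (i in seq_len(n)) {
        state <- if (state) u[i] > p10 else u[i] < p01
        wet[i] <- state
      }
      prec <- ifelse(wet, stats::rexp(n, 1 / 0.49), 0)
    } else {
      # periodic rain pattern, same for every year, annual total ~711 mm
      wet <- (doy %% 4L == 1L) & hour >= 2 & hour < 6.5
      prec <- ifelse(wet, 1.0, 0)
    }

    # clearness index and PAR
    kt <- 0.58 + ar1(nd, 0.6, truth$kt_sd)[day_id] +
      stats::rnorm(n, 0, 0.06 * stoch)
    kt[wet] <- kt[wet] * 0.35
    kt <- pmin(pmax(kt, 0.10), 0.98)
    par <- 2300 * cosz * kt * 0.93
    par[cosz <= 0] <- 0
    fd <- pmin(pmax(1 / (1 + exp(8 * (kt - 0.45))) + 0.08, 0.1), 1)
    fd[wet] <- 1
    rg <- par / 2.1

    # humidity: seasonal + diurnal relative-humidity skeleton
    rh <- 0.84 - 0.10 * cos(2 * pi * (doy - 205) / 365.25) -
      0.26 * cosz + ar1(nd, 0.7, 0.05 * stoch)[day_id]
    rh <- pmin(pmax(rh, 0.25), 1)
    d <- esat_kpa(ta) * (1 - rh)
    d[wet] <- pmin(d[wet], 0.05)
    d <- pmax(d, 0)

    # ambient CO2: trend + seasonal cycle (max in May) + small daily noise
    ca <- truth$ca0 + truth$ca_trend * dy +
      8 * cos(2 * pi * (doy - 130) / 365.25) +
      ar1(nd, 0.7, 1.0 * stoch)[day_id]
    ca <- pmax(ca, 1)

    # soil temperature: one-week damped air temperature, snow floor near 0 C
    ts_soil <- pmax(1.2 + 0.85 * ema(ta, 1 / (48 * 7)), 0)

    # soil water bucket (daily): refilled by rain, drained by demand
    pd <- tapply(prec, day_id, sum)
    dd <- tapply(d, day_id, mean)
    w <- numeric(nd); w[1] <- 0.85
    for (i in 2:nd) {
      demand <- (0.8 + 2.2 * max(dd[i], 0)) / 60
      w[i] <- min(max(w[i - 1] + pd[i] / 60 - demand, 0.05), 1)
    }
    rew <- w[day_id]

    u_wind <- pmax(3.2 + ar1(nd, 0.5, 0.8 * stoch)[day_id] + 0.5 * cosz, 0.3)
    patm <- PATM_KPA + ar1(nd, 0.8, 0.3 * stoch)[day_id]

    out <- data.frame(timestamp = ts, zenith = zen, PAR = par, fd = fd,
                      Rg = rg, Ta = ta, D = d, P = prec, ca = ca,
                      Ts = ts_soil, Rew = rew, U = u_wind, Patm = patm,
                      year = year, doy = doy)
    attr(out, "seed") <- seed
    class(out) <- c("forcing_series", "data.frame")
    out
  })
}

## delayed temperature state and seasonal photosynthetic capacity used by the
## flux truth (sigmoid of a 5-day exponential temperature average)
season_state <- function(ta) ema(ta, 1 / (48 * 5))
season_capacity <- function(state) 1 / (1 + exp(-(state - 6) / 2.2))

#' Generate "observed" fluxes from forcing with known truth
#'
#' The truth GPP is a rectangular-hyperbola light response scaled by a
#' seasonal capacity (sigmoid of 5-day-lagged air temperature) and the
#' injected relative trend; truth respiration is Lloyd-Taylor on soil
#' temperature; truth ET is big-leaf transpiration at a fixed internal-CO2
#' ratio plus a radiation-driven non-stomatal term. Gaussian noise
#' (additive + flux-proportional) is added to form the observations, and the
#' noise-free truth columns are retained for recovery tests.
#'
#' @param forcing a [generate_forcing()] result.
#' @param truth the [truth_params()] used.
#' @param seed integer seed for the noise realization.
#' @return data.frame (`flux_series`): `timestamp`, `NEP`, `ET`, `gap_flag`
#'   plus truth columns `GPP_truth`, `Re_truth`, `NEP_truth`, `ET_truth`.
#'   Units: NEP/GPP/Re umol CO2 m-2 s-1 (NEP positive = uptake), ET mmol
#'   H2O m-2 s-1.
#' @export
generate_observed_fluxes <- function(forcing, truth = truth_params(),
                                     seed = 1L) {
  stopifnot(inherits(forcing, "data.frame"))
  with_seed(seed, {
    n <- nrow(forcing)
    dy <- forcing$year - min(forcing$year)
    fsea <- season_capacity(season_state(forcing$Ta))
    gpp <- (1 + truth$gpp_trend * dy) * fsea *
      truth$alpha_q * forcing$PAR * truth$pmax /
      (truth$alpha_q * forcing$PAR + truth$pmax)
    gpp[forcing$PAR <= 0] <- 0
    re <- lloyd_taylor(forcing$Ts, truth$rref, truth$e0)
    nep_t <- gpp - re
    # transpiration at fixed 1 - ci/ca = 0.15, plus non-stomatal term
    gs_eff <- gpp / (forcing$ca * 0.14)
    tr <- 1.6 * gs_eff * forcing$D / forcing$Patm * 1000   # mmol m-2 s-1
    evap <- 0.05 + 0.20 * pmax(forcing$Rg, 0) / 500 +
      ifelse(forcing$P > 0, 0.4, 0)
    et_t <- tr + evap
    nep <- nep_t + stats::rnorm(n) *
      sqrt(truth$noise_add^2 + (truth$noise_prop * abs(nep_t))^2)
    et <- pmax(et_t + stats::rnorm(n) *
                 sqrt(0.03^2 + (truth$noise_prop * et_t)^2), 0)
    out <- data.frame(timestamp = forcing$timestamp, NEP = nep, ET = et,
                      gap_flag = "observed",
                      GPP_truth = gpp, Re_truth = re, NEP_truth = nep_t,
                      ET_truth = et_t, stringsAsFactors = FALSE)
    attr(out, "seed") <- seed
    class(out) <- c("flux_series", "data.frame")
    out
  })
}

#' Inject clustered gaps into a flux series
#'
#' Marks half-hours missing with geometric run lengths (a two-state Markov
#' chain whose stationary missing fraction equals `truth$gap_fraction` and
#' whose mean gap run is `truth$gap_run` half-hours), emulating the ~34%
#' missing-data burden of long eddy-covariance records.
#'
#' @param series a [generate_observed_fluxes()] result without prior gaps.
#' @param truth the [truth_params()] holding the gap process.
#' @param seed integer seed for the gap mask.
#' @return the series with `NEP`/`ET` set `NA` and `gap_flag = "gap"` at
#'   masked half-hours.
#' @export
inject_gaps <- function(series, truth = truth_params(), seed = 1L) {
  if (truth$gap_fraction >= 1) stop("gap fraction target must be < 1")
  if (any(series$gap_flag != "observed"))
    stop("series has pre-existing gaps")
  if (truth$gap_fraction == 0) return(series)
  with_seed(seed, {
    n <- nrow(series)
    p10 <- 1 / truth$gap_run
    p01 <- p10 * truth$gap_fraction / (1 - truth$gap_fraction)
    u <- stats::runif(n)
    gap <- logical(n); state <- stats::runif(1) < truth$gap_fraction
    for (i in seq_len(n)) {
      state <- if (state) u[i] > p10 else u[i] < p01
      gap[i] <- state
    }
    series$NEP[gap] <- NA_real_
    series$ET[gap] <- NA_real_
    series$gap_flag[gap] <- "gap"
    series
  })
}
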