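## Shared fixtures, generated once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

## two-year stochastic record with observed fluxes (no gaps)
fx_two_year <- function() {
  cached("two_year", {
    tr <- truth_params()
    f <- generate_forcing(tr, 2003:2004, seed = 301)
    o <- generate_observed_fluxes(f, tr, seed = 302)
    list(truth = tr, forcing = f, fluxes = o)
  })
}

## one noise-free, trendless year (deterministic limit)
fx_quiet_year <- function() {
  cached("quiet_year", {
    tr <- truth_params(noise_add = 0, noise_prop = 0, gpp_trend = 0,
                       ca_trend = 0, met_year_sd = 0, weather_sd = 0,
                       kt_sd = 0)
    f <- generate_forcing(tr, 2003, seed = 303)
    o <- generate_observed_fluxes(f, tr, seed = 304)
    list(truth = tr, forcing = f, fluxes = o)
  })
}

## minimal hand-built forcing frame (constant conditions), n days
constant_forcing <- function(n_days = 30, ts_c = 10, ta_c = 10,
                             par_day = 800, year = 2005) {
  ts <- halfhour_grid(year)
  idx <- seq_len(n_days * 48L)
  ts <- ts[idx]
  tp <- list(doy = as.POSIXlt(ts)$yday + 1L,
             hour = as.POSIXlt(ts)$hour + as.POSIXlt(ts)$min / 60)
  day <- tp$hour >= 9 & tp$hour < 15
  f <- data.frame(timestamp = ts, zenith = ifelse(day, 60, 120),
                  PAR = ifelse(day, par_day, 0), fd = 0.3,
                  Rg = ifelse(day, par_day / 2.1, 0), Ta = ta_c, D = 0.8,
                  P = 0, ca = 400, Ts = ts_c, Rew = 0.8, U = 3,
                  Patm = 101.3, year = year, doy = tp$doy)
  class(f) <- c("forcing_series", "data.frame")
  f
}
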