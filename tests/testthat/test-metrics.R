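test_that("surface conductance inverts the transpiration relation", {
  # 4 mmol m-2 s-1 at D = 1 kPa, sea-level pressure
  expect_equal(surface_conductance(0.004, 1.0, 101.3),
               0.004 / (1.6 / 101.3), tolerance = 1e-12)
  expect_equal(surface_conductance(0, 1.0), 0)
  expect_true(is.na(surface_conductance(0.004, 0.01)))   # masked low D
  expect_true(is.na(surface_conductance(-1, 1)))
})

test_that("efficiency identities hold to machine precision", {
  expect_equal(ecosystem_ci_ca(10, 0.2, 400), 0.875)
  expect_equal(iwue(10, 0.2), 50)
  expect_equal(ecosystem_ci_ca(0, 0.2, 400), 1)
  expect_equal(iwue(0, 0.2), 0)
  set.seed(1)
  gpp <- runif(200, 0, 20); gs <- runif(200, 0.01, 0.4)
  ca <- runif(200, 350, 420)
  # IWUE == ca (1 - CiCa) == GPP/Gs identically
  expect_equal(iwue(gpp, gs), ca * (1 - ecosystem_ci_ca(gpp, gs, ca)),
               tolerance = 1e-12)
  expect_true(all(ecosystem_ci_ca(gpp, gs, ca) <= 1))
})

test_that("ratio of sums equals mean of ratios only for constant fluxes", {
  gpp <- rep(8, 100); et <- rep(2, 100)
  expect_equal(wue(sum(gpp), sum(et)), mean(wue(gpp, et)))
  expect_equal(lue(sum(gpp), sum(rep(400, 100))),
               mean(lue(gpp, rep(400, 100))))
})

test_that("dry-canopy mask follows the lookback window arithmetic", {
  p <- rep(0, 200)
  m0 <- dry_canopy_mask(p, 12)
  expect_true(all(m0[25:200]))           # dry once the lookback is complete
  expect_true(all(!m0[1:24]))            # unknown head treated wet
  p[100] <- 1.5                          # single rain event
  m <- dry_canopy_mask(p, 12)
  expect_false(any(m[100:124]))          # wet through t + 12 h
  expect_true(m[125])                    # dry at t + 12.5 h
  expect_equal(dry_canopy_mask(p, 0), p == 0)
  expect_error(dry_canopy_mask(c(p, NA)), "complete")
})

test_that("carbon uptake period brackets the positive-NEP season", {
  doy <- 1:365
  nep <- sin(pi * (doy - 110) / 160)     # positive exactly on (110, 270)
  nep[doy < 110 | doy > 270] <- -abs(nep[doy < 110 | doy > 270]) - 0.05
  cup <- detect_cup(nep)
  expect_lt(abs(cup[["SCU"]] - 110), 3.5)
  expect_lt(abs(cup[["ECU"]] - 270), 3.5)
  expect_equal(cup[["CUP"]], cup[["ECU"]] - cup[["SCU"]])
  all_neg <- detect_cup(rep(-1, 365))
  expect_true(all(is.na(all_neg)))
})

test_that("thermal growing season detects the +5 C crossings", {
  ta <- ifelse(1:365 >= 120 & 1:365 <= 280, 10, -5)
  gs <- thermal_growing_season(ta)
  expect_equal(gs[["GS_start"]], 120)
  expect_equal(gs[["GS_end"]], 280)
  expect_true(all(is.na(thermal_growing_season(rep(0, 365)))))
  # smooth sinusoid: detected dates equal analytic crossings within the
  # spell length
  doy <- 1:365
  ta2 <- 4 + 11 * cos(2 * pi * (doy - 205) / 365)
  cross <- range(doy[ta2 > 5])
  gs2 <- thermal_growing_season(ta2)
  expect_lt(abs(gs2[["GS_start"]] - cross[1]), 5.5)
  expect_lt(abs(gs2[["GS_end"]] - cross[2]), 5.5)
})

test_that("light-response fit recovers exact hyperbolic parameters", {
  a <- 0.04; pm <- 18
  par <- seq(100, 1700, by = 200)
  gpp <- pm * a * par / (pm + a * par)
  cf <- fit_light_response(par, gpp)
  expect_lt(abs(cf[["alpha"]] - a), 1e-6)
  expect_lt(abs(cf[["pmax"]] - pm), 1e-6)
})

test_that("binned analysis localizes a high-PAR trend", {
  # constructed truth: GPP hyperbolic in PAR; only PAR > 700 carries a
  # +1% a-1 multiplicative trend
  set.seed(42)
  years <- 2001:2010
  rows <- list()
  for (y in years) {
    ts <- halfhour_grid(y)
    sel <- as.POSIXlt(ts)$mon == 6      # July
    ts <- ts[sel][1:600]
    par <- runif(600, 50, 1750)
    gpp <- 20 * 0.05 * par / (20 + 0.05 * par)
    hi <- par > 700
    gpp[hi] <- gpp[hi] * (1 + 0.01 * (y - years[1]))
    rows[[length(rows) + 1L]] <- data.frame(
      timestamp = ts, year = y, PAR = par, GPP = gpp,
      P = 0, Rew = 0.8)
  }
  df <- do.call(rbind, rows)
  forcing <- df[c("timestamp", "year", "PAR", "P", "Rew")]
  series <- df[c("timestamp", "GPP")]
  lr <- light_response_binned(series, forcing, period = c("07-01", "07-31"))
  bm <- lr$bin_means
  lev <- unique(bm$bin)                  # ordered with the bin edges
  trend_p <- vapply(lev, function(lv) {
    b <- bm[bm$bin == lv & is.finite(bm$GPP), ]
    if (nrow(b) < 5) return(NA_real_)
    linear_trend(b$GPP, b$year)$p
  }, numeric(1))
  lo <- trend_p[1:3]                     # PAR < 600
  hi <- trend_p[5:9]                     # PAR > 800
  expect_true(all(na.omit(lo) > 0.05))
  expect_true(any(na.omit(hi) < 0.05))
})
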