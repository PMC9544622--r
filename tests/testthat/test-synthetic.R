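test_that("generated forcing satisfies the physical invariants", {
  f <- fx_two_year()$forcing
  expect_true(all(f$PAR >= 0))
  expect_true(all(f$PAR[f$zenith >= 90] == 0))
  expect_true(all(f$fd >= 0 & f$fd <= 1))
  expect_true(all(f$D >= 0))
  expect_true(all(f$P >= 0))
  expect_true(all(f$ca > 0))
  expect_true(all(f$Rew >= 0 & f$Rew <= 1))
  dt <- diff(as.numeric(f$timestamp))
  expect_true(all(dt == 1800))         # complete, strictly increasing grid
  expect_equal(nrow(f), (365 + 366) * 48)
})

test_that("generator output is a pure function of the seed", {
  tr <- truth_params()
  f1 <- generate_forcing(tr, 2003, seed = 11)
  f2 <- generate_forcing(tr, 2003, seed = 11)
  f3 <- generate_forcing(tr, 2003, seed = 12)
  expect_identical(f1, f2)
  expect_false(identical(f1$Ta, f3$Ta))
  o1 <- generate_observed_fluxes(f1, tr, seed = 5)
  o2 <- generate_observed_fluxes(f1, tr, seed = 5)
  expect_identical(o1, o2)
})

test_that("the configured CO2 trend is injected faithfully", {
  f <- cached("f17", generate_forcing(truth_params(), 2001:2017, seed = 77))
  ca_y <- tapply(f$ca, f$year, mean)
  yrs <- as.numeric(names(ca_y))
  sl <- unname(coef(lm(ca_y ~ yrs))[2])
  expect_lt(abs(sl - 2.3), 0.05)
  # boreal climate envelope
  ta_y <- tapply(f$Ta, f$year, mean)
  expect_true(all(ta_y > 2.5 & ta_y < 5.7))
  p_y <- tapply(f$P, f$year, sum)
  expect_gt(mean(p_y), 550); expect_lt(mean(p_y), 900)
})

test_that("noise-free trendless configuration is cyclostationary", {
  tr <- fx_quiet_year()$truth
  f <- generate_forcing(tr, 2005:2007, seed = 1)   # non-leap years
  # identical up to the leap-cycle drift of the solar ephemeris (~0.03%)
  for (v in c("Ta", "PAR", "ca", "D", "P")) {
    m <- tapply(f[[v]], f$year, mean)
    expect_lt(diff(range(m)) / max(abs(mean(m)), 1e-6), 1e-3)
  }
  # noise-free trend injection is exact: slope of annual ca equals config
  tr2 <- truth_params(noise_add = 0, noise_prop = 0, met_year_sd = 0,
                      weather_sd = 0, kt_sd = 0, ca_trend = 2.3)
  f2 <- generate_forcing(tr2, 2005:2007, seed = 1)
  ca_y <- tapply(f2$ca, f2$year, mean)
  sl <- unname(coef(lm(ca_y ~ as.numeric(names(ca_y))))[2])
  expect_lt(abs(sl / 2.3 - 1), 1e-9)
})

test_that("flux truth obeys the dark limit and conservation", {
  q <- fx_quiet_year()
  o <- q$fluxes
  # conservation of the truth decomposition
  expect_equal(o$GPP_truth - o$Re_truth, o$NEP_truth, tolerance = 1e-12)
  # dark limit: no PAR means NEP = -Re exactly (zero noise)
  dark <- q$forcing$PAR == 0
  expect_true(all(o$GPP_truth[dark] == 0))
  expect_equal(o$NEP[dark], -o$Re_truth[dark], tolerance = 1e-12)
  expect_true(all(o$GPP_truth >= 0) && all(o$Re_truth > 0))
})

test_that("annual truth GPP is identical across years without trends", {
  tr <- fx_quiet_year()$truth
  f <- generate_forcing(tr, 2005:2007, seed = 2)
  o <- generate_observed_fluxes(f, tr, seed = 3)
  g <- tapply(o$GPP_truth, f$year, sum)
  # equal up to the season-state spin-up in year 1 and the leap-cycle
  # solar phase drift (~0.1%)
  expect_lt(diff(range(g)) / mean(g), 5e-3)
})

test_that("gap injection hits the target fraction with clustered runs", {
  x <- fx_two_year()
  tr <- x$truth
  g <- inject_gaps(x$fluxes, tr, seed = 21)
  frac <- mean(g$gap_flag == "gap")
  expect_lt(abs(frac - 0.336), 0.02)
  expect_true(all(is.na(g$NEP[g$gap_flag == "gap"])))
  # clustered: mean run length near the configured geometric mean
  r <- rle(g$gap_flag == "gap")
  mean_run <- mean(r$lengths[r$values])
  expect_gt(mean_run, 3); expect_lt(mean_run, 12)
  # seeding contract
  g2 <- inject_gaps(x$fluxes, tr, seed = 21)
  expect_identical(which(is.na(g$NEP)), which(is.na(g2$NEP)))
  # trivial and error paths
  expect_identical(inject_gaps(x$fluxes, truth_params(gap_fraction = 0), 1),
                   x$fluxes)
  expect_error(inject_gaps(x$fluxes, truth_params(gap_fraction = 0.99999)),
               NA)
  tr_bad <- truth_params(); tr_bad$gap_fraction <- 1
  expect_error(inject_gaps(x$fluxes, tr_bad, 1), "< 1")
})

test_that("zero-length year range is rejected", {
  expect_error(generate_forcing(truth_params(), integer(0)), "year")
})
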