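test_that("Lloyd-Taylor parameters are recovered from exact model data", {
  temp <- seq(0, 20, by = 0.5)
  resp <- lloyd_taylor(temp, 2.0, 150)
  fit <- fit_lloyd_taylor(temp, resp)
  expect_false(fit$e0_fixed)
  expect_lt(abs(coef(fit)[["rref"]] - 2.0), 1e-6)
  expect_lt(abs(coef(fit)[["e0"]] - 150), 1e-4)
  expect_lt(fit$rmse, 1e-8)
  expect_equal(predict(fit, temp), resp, tolerance = 1e-7)
})

test_that("isothermal data fall back to an Rref-only fit", {
  temp <- rep(15, 40)
  resp <- rnorm(40, 3, 0.1)
  fit <- fit_lloyd_taylor(temp, resp, e0_fallback = 100)
  expect_true(fit$e0_fixed)
  # at T = Tref the Lloyd-Taylor factor is 1, so Rref = mean(resp)
  expect_equal(coef(fit)[["rref"]], mean(resp), tolerance = 1e-10)
  # and without a fallback the caller gets a window-skip signal
  expect_null(fit_lloyd_taylor(temp[1:5], resp[1:5]))
})

test_that("two noise-free points invert to the closed-form E0", {
  t1 <- 5; t2 <- 15; t0 <- -46.02
  r1 <- lloyd_taylor(t1, 1.7, 210); r2 <- lloyd_taylor(t2, 1.7, 210)
  # algebraic inversion of the exponential form
  e0_closed <- log(r2 / r1) / (1 / (t1 - t0) - 1 / (t2 - t0))
  expect_equal(e0_closed, 210, tolerance = 1e-9)
  fit <- fit_lloyd_taylor(c(t1, t2), c(r1, r2), min_pairs = 2)
  expect_lt(abs(coef(fit)[["e0"]] - e0_closed), 1e-4)
})

test_that("fitted respiration is strictly increasing in temperature", {
  temp <- seq(-5, 25, by = 1)
  fit <- fit_lloyd_taylor(temp, lloyd_taylor(temp, 2.5, 120) +
                            rnorm(length(temp), 0, 0.05))
  pr <- predict(fit, seq(-10, 30, by = 0.1))
  expect_true(all(diff(pr) > 0))
})

test_that("constant conditions give constant Re and shifted GPP", {
  f <- constant_forcing(40, ts_c = 10, ta_c = 10)
  nep <- ifelse(f$PAR > 0, 6, -2)   # constant nighttime efflux of 2
  o <- data.frame(timestamp = f$timestamp, NEP = nep, ET = 1,
                  gap_flag = "observed", stringsAsFactors = FALSE)
  p <- suppressWarnings(partition_nighttime(o, f, "Ts"))
  day <- f$PAR >= 20
  expect_equal(unique(round(p$Re[day], 8)), 2)
  expect_equal(p$GPP[day], nep[day] + 2, tolerance = 1e-8)
  expect_true(all(p$GPP[!day] == 0))
  # half-hourly identity everywhere (night Re balances NEP)
  expect_equal(p$GPP - p$Re, p$NEP, tolerance = 1e-10)
})

test_that("annual GPP is recovered within 5% on synthetic data", {
  x <- fx_two_year()
  p_ts <- cached("part_ts", partition_nighttime(x$fluxes, x$forcing, "Ts"))
  p_ta <- cached("part_ta", partition_nighttime(x$fluxes, x$forcing, "Ta"))
  to_g <- function(v, yy) tapply(v * 1800 * 12.011e-6, yy, sum)
  yy <- x$forcing$year
  g_true <- to_g(x$fluxes$GPP_truth, yy)
  g_ts <- to_g(p_ts$GPP, yy)
  g_ta <- to_g(p_ta$GPP, yy)
  expect_true(all(abs(g_ts / g_true - 1) < 0.05))
  expect_true(all(abs(g_ta / g_true - 1) < 0.10))
})

test_that("partitioning is idempotent", {
  x <- fx_two_year()
  p1 <- cached("part_ts", partition_nighttime(x$fluxes, x$forcing, "Ts"))
  p2 <- partition_nighttime(p1, x$forcing, "Ts")
  expect_equal(p2$GPP, p1$GPP, tolerance = 1e-12)
  expect_equal(p2$Re, p1$Re, tolerance = 1e-12)
})

test_that("aggregation conserves carbon and converts units exactly", {
  x <- fx_two_year()
  p <- cached("part_ts", partition_nighttime(x$fluxes, x$forcing, "Ts"))
  for (per in list("annual", "may_sep", c("07-01", "08-10"))) {
    a <- aggregate_fluxes(p, x$forcing, per)
    expect_equal(a$GPP - a$Re, a$NEP, tolerance = 1e-9)
  }
  # unit arithmetic on a constant series over a non-leap year
  f1 <- x$forcing[x$forcing$year == 2003, ]
  o1 <- data.frame(timestamp = f1$timestamp, NEP = 1, ET = 0,
                   gap_flag = "observed", stringsAsFactors = FALSE)
  a1 <- aggregate_fluxes(o1, f1, "annual")
  expect_equal(a1$NEP, 1e-6 * 12.011 * 86400 * 365, tolerance = 1e-9)
  expect_error(aggregate_fluxes(o1, f1, c("13-01", "13-10")), "zero")
})
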