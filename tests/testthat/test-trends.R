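test_that("Sen slope handles flat, linear and degenerate input", {
  expect_equal(sen_slope(c(5, 5, 5, 5)), 0)
  expect_equal(sen_slope(c(1, 2, 3, 4)), 1)
  expect_error(sen_slope(c(1, 2)), "3 non-missing")
  # pairwise deletion of missing years
  expect_equal(sen_slope(c(1, NA, 3, 4), c(1, 2, 3, 4)), 1)
})

test_that("Sen slope equals the brute-force pairwise median on random input", {
  brute <- function(y, t) {
    s <- c()
    for (i in seq_along(y)[-length(y)])
      for (j in (i + 1):length(y))
        s <- c(s, (y[j] - y[i]) / (t[j] - t[i]))
    median(s)
  }
  set.seed(7)
  for (rep in 1:200) {
    n <- sample(3:20, 1)
    y <- rnorm(n); t <- sort(sample(1:50, n))
    expect_equal(sen_slope(y, t), brute(y, t), tolerance = 1e-12)
  }
})

test_that("Sen slope is shift-invariant and scale-equivariant", {
  set.seed(8)
  y <- rnorm(15); t <- 1:15
  s <- sen_slope(y, t)
  expect_equal(sen_slope(y + 100, t), s, tolerance = 1e-12)
  expect_equal(sen_slope(3 * y, t), 3 * s, tolerance = 1e-12)
})

test_that("linear trend matches the normal-equation closed form", {
  tr <- suppressWarnings(linear_trend(c(0, 1, 2), c(0, 1, 2)))
  expect_equal(tr$ols_slope, 1); expect_equal(tr$r2, 1)
  set.seed(9)
  y <- rnorm(17); t <- 2001:2017
  tr2 <- linear_trend(y, t)
  slope_closed <- sum((t - mean(t)) * (y - mean(y))) / sum((t - mean(t))^2)
  expect_equal(tr2$ols_slope, slope_closed, tolerance = 1e-12)
  expect_equal(tr2$iav_sd, sd(y - mean(y) - slope_closed * (t - mean(t))),
               tolerance = 1e-12)
  expect_error(linear_trend(y, rep(2001, 17)), "constant")
})

test_that("de-trending returns zero-mean residuals and inverts construction", {
  expect_equal(detrend(2 * (1:10) + 3), rep(0, 10), tolerance = 1e-12)
  set.seed(10)
  res_true <- rnorm(12); res_true <- res_true - mean(res_true)
  t <- 1:12
  res_true <- res_true - sum(res_true * (t - mean(t))) /
    sum((t - mean(t))^2) * (t - mean(t))  # orthogonal to the trend
  y <- 5 + 0.7 * t + res_true
  expect_equal(detrend(y, t), res_true, tolerance = 1e-10)
  expect_lt(abs(mean(detrend(y, t))), 1e-12)
})

test_that("moving window means obey the window algebra", {
  yrs <- rep(2001:2002, each = 365)
  daily <- data.frame(year = yrs, doy = rep(1:365, 2), value = 2.5)
  m <- moving_window_annual(daily)
  expect_true(all(abs(m[16:350, ] - 2.5) < 1e-12))
  # an impulse of +31 spreads over exactly 31 center days with mean 1
  daily2 <- daily; daily2$value <- 0
  daily2$value[daily2$year == 2001 & daily2$doy == 180] <- 31
  m2 <- moving_window_annual(daily2)
  expect_equal(sum(m2[, "2001"] == 1, na.rm = TRUE), 31)
  expect_true(all(m2[c(164, 196), "2001"] == 0))
  # symmetric window: linear-in-doy series reproduces the center value
  daily3 <- daily; daily3$value <- daily3$doy * 0.1
  m3 <- moving_window_annual(daily3)
  expect_equal(m3[100, "2001"], 10, tolerance = 1e-9)
})

test_that("partial correlation reduces to closed forms", {
  set.seed(11)
  x <- rnorm(40); y <- x
  expect_equal(partial_correlation(y, x)[["rp"]], 1, tolerance = 1e-12)
  # three-variable recursive identity on random data
  for (i in 1:20) {
    y <- rnorm(30); x <- rnorm(30); z <- rnorm(30) + 0.5 * x + 0.3 * y
    rxy <- cor(y, x); rxz <- cor(y, z); ryz <- cor(x, z)
    rp_closed <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
    rp_pkg <- partial_correlation(y, x, cbind(z))[["rp"]]
    expect_equal(rp_pkg, rp_closed, tolerance = 1e-12)
  }
  # independence null: |rp| small for n = 1000
  y <- rnorm(1000); x <- rnorm(1000)
  expect_lt(abs(partial_correlation(y, x)[["rp"]]), 0.08)
})

test_that("critical correlation thresholds match the t-quantile formula", {
  expect_equal(round(critical_r(17, 0.1, 0), 2), 0.41)
  expect_equal(critical_r(10, 0.05, 0),
               qt(0.975, 8) / sqrt(qt(0.975, 8)^2 + 8), tolerance = 1e-12)
  expect_equal(round(critical_r(10, 0.05, 0), 3), 0.632)
  expect_lt(critical_r(17, 0.9999), 0.01)
  expect_error(critical_r(3, 0.05, 1), "df|>=")
})

test_that("detection limit follows the autocorrelation-inflated formula", {
  expect_equal(detection_limit(0, 0, 17), 0)
  expect_equal(detection_limit(50, 0, 17), 3.3 * 50 / 17^1.5,
               tolerance = 1e-12)
  expect_gt(detection_limit(50, 0.4, 17), detection_limit(50, 0, 17))
  expect_error(detection_limit(50, 1, 17), "phi")
})

test_that("window partial-correlation analysis flags an injected driver", {
  set.seed(12)
  years <- 2001:2017
  drv <- data.frame(year = rep(years, each = 365),
                    doy = rep(1:365, length(years)),
                    value = rnorm(365 * length(years)))
  resp <- drv
  resp$value <- 0.9 * drv$value + rnorm(nrow(drv), 0, 0.3)
  other <- drv; other$value <- rnorm(nrow(drv))
  out <- iav_driver_correlation(resp, list(ta = drv, par = other))
  ta_rows <- out[out$driver == "ta", ]
  par_rows <- out[out$driver == "par", ]
  expect_gt(mean(ta_rows$significant), 0.9)
  expect_lt(mean(par_rows$significant), 0.3)
})
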