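hourly_times <- function(n, start = "2018-01-01") {
  as.POSIXct(start, tz = "UTC") + 3600 * (0:(n - 1))
}

test_that("burst averaging takes the mean of unmasked samples", {
  expect_equal(burst_average(c(1, 1, 1, 1, 1))$value, 1)
  expect_equal(burst_average(c(0, 2, 4, 6, 8))$value, 4)
  # 8-sample burst with 2 masked, unmasked mean 3.5
  v <- c(2, 3, 4, 5, 3, 4, 100, 200)
  qc <- c(rep("ok", 6), "blowdown", "missing")
  expect_equal(burst_average(v, qc)$value, 3.5)
  empty <- burst_average(numeric(0))
  expect_true(is.na(empty$value))
  expect_identical(empty$qc_flag, "missing")
})

test_that("blow-down masking flags large downward excursions only", {
  ms <- mooring_series(hourly_times(3), c(1, 2, 3), nominal_depth = 30,
                       actual_depth = c(230, 31, 30), units = "degC")
  out <- mask_blowdowns(ms, threshold_m = 10)
  expect_identical(out$qc_flag, c("blowdown", "ok", "ok"))
  # threshold 0 with actual == nominal flags nothing
  ms2 <- mooring_series(hourly_times(3), 1:3, nominal_depth = 30,
                        actual_depth = rep(30, 3), units = "degC")
  expect_identical(mask_blowdowns(ms2, 0)$qc_flag, rep("ok", 3))
  # no actual_depth: warning, unchanged
  ms3 <- mooring_series(hourly_times(3), 1:3, nominal_depth = 30)
  expect_warning(out3 <- mask_blowdowns(ms3), "actual_depth")
  expect_identical(out3$qc_flag, ms3$qc_flag)
})

test_that("lowpass preserves DC and the mean, attenuates per transfer fn", {
  n <- 120 * 24
  const <- mooring_series(hourly_times(n), rep(3.7, n), units = "1")
  out <- lowpass_filter(const)
  expect_equal(out$value, rep(3.7, n), tolerance = 1e-9)

  expect_lt(sinusoid_attenuation(period_days = 1), 1 / 10)
  expect_gt(sinusoid_attenuation(period_days = 30), 0.95)

  # mean preserved on a broadband series
  set.seed(1)
  v <- cumsum(rnorm(n, 0, 0.1)) + 5
  ms <- mooring_series(hourly_times(n), v, units = "1")
  expect_equal(mean(lowpass_filter(ms)$value), mean(v), tolerance = 1e-3)
})

test_that("lowpass is linear and rejects too-short series", {
  n <- 60 * 24
  set.seed(2)
  x <- rnorm(n); y <- rnorm(n)
  msx <- mooring_series(hourly_times(n), x, units = "1")
  msy <- mooring_series(hourly_times(n), y, units = "1")
  msz <- mooring_series(hourly_times(n), 2 * x + 3 * y, units = "1")
  lhs <- lowpass_filter(msz)$value
  rhs <- 2 * lowpass_filter(msx)$value + 3 * lowpass_filter(msy)$value
  expect_equal(lhs, rhs, tolerance = 1e-9)

  short <- mooring_series(hourly_times(100), rnorm(100), units = "1")
  expect_error(lowpass_filter(short), "shorter")
})

test_that("lowpass interpolates short gaps and propagates long ones", {
  n <- 120 * 24
  v <- rep(1, n)
  v[500:503] <- NA          # 4 h gap: bridged
  v[2000:2020] <- NA        # 21 h gap: propagates
  ms <- mooring_series(hourly_times(n), v, units = "1")
  out <- lowpass_filter(ms)
  expect_false(anyNA(out$value[500:503]))
  expect_true(all(is.na(out$value[2000:2020])))
})

test_that("daily mean applies the minimum-sample rule", {
  n <- 48
  v <- c(rep(2, 24), rep(0, 12), rep(2, 12))
  ms <- mooring_series(hourly_times(n), v, units = "1")
  dm <- daily_mean(ms)
  expect_equal(dm$value, c(2, 1))
  # day with only 2 valid samples is missing at min 6
  v2 <- c(rep(NA, 22), 5, 5, rep(1, 24))
  ms2 <- mooring_series(hourly_times(n), v2, units = "1")
  dm2 <- daily_mean(ms2, min_samples = 6)
  expect_true(is.na(dm2$value[1]))
  expect_equal(dm2$value[2], 1)
})

test_that("masked samples never change downstream statistics", {
  n <- 48
  v <- rnorm(n)
  qc <- rep("ok", n); qc[c(5, 17, 30)] <- "blowdown"
  ms1 <- mooring_series(hourly_times(n), v, units = "1", qc_flag = qc)
  v2 <- v; v2[c(5, 17, 30)] <- 1e6  # perturb masked values only
  ms2 <- mooring_series(hourly_times(n), v2, units = "1", qc_flag = qc)
  expect_equal(daily_mean(ms1)$value, daily_mean(ms2)$value)
})

test_that("CSV round trip is bit-exact in values and flags", {
  n <- 30
  v <- rnorm(n) * exp(rnorm(n, 0, 5))
  qc <- sample(c("ok", "below_detection", "blowdown", "missing"), n,
               replace = TRUE)
  v[qc == "missing"] <- NA
  ms <- mooring_series(hourly_times(n), v, variable = "pCO2", units = "uatm",
                       nominal_depth = 30, actual_depth = 30 + abs(rnorm(n)),
                       qc_flag = qc)
  path <- tempfile(fileext = ".csv")
  write_mooring_csv(ms, path)
  back <- read_mooring_csv(path)
  expect_identical(back$value, ms$value)
  expect_identical(back$qc_flag, ms$qc_flag)
  expect_identical(back$actual_depth, ms$actual_depth)
  expect_equal(back$time, ms$time)
  expect_identical(attr(back, "units"), "uatm")
  expect_identical(attr(back, "nominal_depth"), 30)
})

test_that("mooring_series validates its invariants", {
  expect_error(mooring_series(hourly_times(3)[c(1, 3, 2)], 1:3), "increasing")
  expect_error(mooring_series(hourly_times(2), 1:2, units = ""), "units")
  expect_error(mooring_series(hourly_times(2), 1:2, qc_flag = c("ok", "bad")),
               "qc_flag")
})
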