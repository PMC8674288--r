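test_that("bloom onset requires persistent positive heat flux", {
  dates <- as.Date("2018-03-01") + 0:120
  flux <- ifelse(dates >= as.Date("2018-05-01"), 40, -60)
  expect_equal(detect_bloom_onset(dates, flux), as.Date("2018-05-01"))
  # 3-day positive excursion does not qualify at persistence 5
  flux2 <- flux
  flux2[dates >= as.Date("2018-04-01") & dates <= as.Date("2018-04-03")] <- 20
  expect_equal(detect_bloom_onset(dates, flux2), as.Date("2018-05-01"))
  # always-positive series: first date
  expect_equal(detect_bloom_onset(dates, rep(5, 121)), dates[1])
  expect_error(detect_bloom_onset(dates, rep(-5, 121)), "no date")
})

test_that("bloom end is the first nitrate-depleted date, or missing", {
  dates <- as.Date("2018-05-01") + 0:90
  nit <- pmax(0.5, 12 - 0.3 * as.numeric(dates - dates[1]))
  end <- detect_bloom_end(dates, nit)
  expect_equal(end, dates[which(nit < 1)[1]])
  expect_true(is.na(detect_bloom_end(dates, rep(5, 91))))
  expect_true(is.na(detect_bloom_end(dates, nit, depletion_threshold = 0)))
})

test_that("e-folding growth rate is recovered from exponential chlorophyll", {
  dates <- as.Date("2018-05-01") + 0:13
  chl <- 0.1 * exp(0.2 * (0:13))
  fit <- suppressWarnings(efolding_growth_rate(dates, chl))
  expect_equal(fit$rate, 0.2, tolerance = 1e-10)
  # with seeded 10% multiplicative noise, within +-0.05
  g <- synthetic_growth_series(rate = 0.2, days = 14, noise_sd = 0.1, seed = 42)
  fitn <- efolding_growth_rate(g$date, g$chl)
  expect_lt(abs(fitn$rate - 0.2), 0.05)
  # constant series has zero growth
  expect_equal(suppressWarnings(efolding_growth_rate(dates, rep(2, 14)))$rate, 0)
  # non-positive values are excluded with a warning
  chl2 <- chl; chl2[3] <- 0
  expect_warning(efolding_growth_rate(dates, chl2), "non-positive")
})

test_that("stoichiometry regressions recover exact linear couplings", {
  dates <- as.Date("2018-05-01") + 0:30
  x <- seq(0, 12, length.out = 31)
  daily <- data.frame(date = dates, nitrate = 12 - x, aou = -7 * x,
                      pco2 = 400 - 15 * x, chl = 0.6 * x)
  fits <- stoichiometry_regressions(daily, c(dates[1], dates[31]))
  expect_equal(fits$bloom$aou_vs_nitrate$m, 7, tolerance = 1e-10)
  expect_equal(fits$bloom$aou_vs_nitrate$r2, 1, tolerance = 1e-10)
  expect_equal(fits$bloom$chl_vs_nitrate$m, -0.6, tolerance = 1e-10)
  expect_error(stoichiometry_regressions(daily, c(dates[1], dates[5])),
               "fewer than")
})

test_that("noisy synthetic blooms recover the built-in couplings (100 seeds)", {
  slopes <- vapply(1:100, function(seed) {
    ml <- generate_scenario(scenario_config("ML", seed = seed), noise = TRUE,
                            hourly = FALSE)
    fits <- stoichiometry_regressions(
      ml$daily, c(ml$config$bloom_start, ml$config$bloom_end))
    fits$bloom$aou_vs_nitrate$m
  }, numeric(1))
  # unbiased to ~1.5% and precise: the sampling spread of a single-season
  # fit under AR(1) sensor noise stays well below the coupling itself
  expect_lt(abs(mean(slopes) - 7), 0.1)
  expect_lt(sd(slopes), 0.5)
  expect_gte(mean(abs(slopes - 7) < 2 * sd(slopes)), 0.9)
})

test_that("regime classification partitions and matches the cell oracle", {
  expect_identical(classify_regime(10, 4.5), "MW")
  expect_identical(classify_regime(45, 0.2), "ML")
  expect_identical(classify_regime(60, 2.0), "unstratified")
  expect_identical(classify_regime(45, 1.0), "ML")  # boundary: equality to ML
  set.seed(21)
  mld <- runif(500, 0, 120)
  ds <- runif(500, 0, 3)
  cls <- classify_regime(mld, ds)
  expect_true(all(cls %in% c("MW", "ML", "unstratified")))
  area <- runif(500, 10, 30)
  ra <- regime_area(mld, ds, area)
  expect_equal(sum(ra), sum(area))
  # brute-force enumeration oracle
  want <- c(MW = 0, ML = 0, unstratified = 0)
  for (i in seq_along(mld)) {
    cl <- if (mld[i] < 50 && ds[i] > 1) "MW"
          else if (mld[i] < 50) "ML" else "unstratified"
    want[cl] <- want[cl] + area[i]
  }
  expect_equal(ra, want)
})

test_that("export lag finds post-onset flux peaks per depth", {
  onset <- as.Date("2018-05-01")
  dates <- as.Date("2018-03-01") + 0:300
  tt <- as.numeric(dates - onset)
  flux <- data.frame(
    date = rep(dates, 2),
    depth = rep(c(200, 2600), each = length(dates)),
    flux = c(10 + 100 * dnorm(tt, 17, 5), 10 + 100 * dnorm(tt, 42, 9))
  )
  el <- export_lag(onset, flux)
  expect_equal(el$lag_days, c(17, 42))
  expect_equal(el$lag_weeks[2], 6)
  expect_true(el$lag_weeks[2] >= 4 && el$lag_weeks[2] <= 7)
  expect_equal(attr(el, "retention_months"), 42 / 30.44)
  # monotone-decreasing flux peaks at the onset: zero lag
  dec <- data.frame(date = dates, depth = 200,
                    flux = 1000 - as.numeric(dates - dates[1]))
  expect_equal(export_lag(onset, dec)$lag_days, 0)
})

test_that("date outputs are invariant to shifting the whole dataset", {
  dates <- as.Date("2018-03-01") + 0:150
  flux <- ifelse(dates >= as.Date("2018-05-01"), 40, -60)
  o1 <- detect_bloom_onset(dates, flux)
  o2 <- detect_bloom_onset(dates + 17, flux)
  expect_equal(as.numeric(o2 - o1), 17)
})
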