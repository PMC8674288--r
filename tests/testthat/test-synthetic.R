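test_that("scenario generation is deterministic given the seed", {
  a <- generate_scenario(scenario_config("ML", seed = 7), hourly = FALSE)
  b <- generate_scenario(scenario_config("ML", seed = 7), hourly = FALSE)
  expect_identical(a$daily, b$daily)
  expect_identical(a$traps, b$traps)
  c <- generate_scenario(scenario_config("ML", seed = 8), hourly = FALSE)
  expect_false(identical(a$daily$nitrate, c$daily$nitrate))
  # different seeds share the identical noiseless backbone
  a0 <- generate_scenario(scenario_config("ML", seed = 7), noise = FALSE,
                          hourly = FALSE)
  c0 <- generate_scenario(scenario_config("ML", seed = 8), noise = FALSE,
                          hourly = FALSE)
  expect_identical(a0$daily, c0$daily)
})

test_that("the noiseless ML backbone hits the configured magnitudes", {
  ml <- generate_scenario(scenario_config("ML"), noise = FALSE, hourly = FALSE)
  d <- ml$daily
  expect_equal(max(d$chl), 7)
  expect_equal(min(d$pco2), 400 - 180)
  expect_equal(max(d$nitrate), 12, tolerance = 0.01)
  expect_lt(min(d$nitrate), 1)
  # built-in coupling: dAOU/dNO3 = 7 exactly over the bloom
  i0 <- which(d$date == as.Date("2018-05-01"))
  i1 <- which(d$date == as.Date("2018-06-15"))
  expect_equal((d$aou[i1] - d$aou[i0]) / (d$nitrate[i1] - d$nitrate[i0]), 7,
               tolerance = 1e-9)
  # nitrate depletion on the configured end date
  expect_equal(detect_bloom_end(d$date, d$nitrate,
                                onset = as.Date("2018-05-01")),
               as.Date(ml$config$bloom_end))
  # PAR at 30 m shaded by ~2 orders of magnitude during the bloom
  mw <- generate_scenario(scenario_config("MW"), noise = FALSE, hourly = FALSE)
  dm <- mw$daily
  pre <- dm$par30[dm$date == as.Date("2018-04-20")]
  mid <- min(dm$par30[dm$date >= as.Date("2018-06-10") &
                        dm$date <= as.Date("2018-07-10")])
  expect_gt(pre / mid, 30)
  # MW nitrate never depletes at 30 m
  expect_true(is.na(detect_bloom_end(dm$date, dm$nitrate)))
})

test_that("noiseless forcing crosses zero on the onset date", {
  f <- generate_forcing("ML", span = c("2018-01-01", "2018-12-31"),
                        noise = FALSE)
  onset <- detect_bloom_onset(as.Date(f$time), f$q_net)
  expect_equal(onset, as.Date("2018-05-01"))
  # annual mean of the noiseless seasonal cycle is (close to) zero
  expect_lt(abs(mean(f$q_net)), 3)
})

test_that("AR(1) noise has the configured lag-1 autocorrelation", {
  set.seed(99)
  x <- moorbloom:::ar1_noise(730, 0.8, 2)
  expect_equal(cor(x[-1], x[-730]), 0.8, tolerance = 0.05)
  expect_equal(sd(x), 2, tolerance = 0.3)
})

test_that("averaging many seeds converges to the noiseless backbone", {
  cfg0 <- scenario_config("ML")
  back <- generate_scenario(cfg0, noise = FALSE, hourly = FALSE)$daily$nitrate
  acc <- 0
  nseed <- 50
  for (s in seq_len(nseed)) {
    acc <- acc + generate_scenario(scenario_config("ML", seed = s),
                                   hourly = FALSE)$daily$nitrate
  }
  rms <- sqrt(mean((acc / nseed - back)^2))
  expect_lt(rms, 3 * 0.3 / sqrt(nseed))
})

test_that("fixture write produces a readable manifest and round-trips", {
  dir <- file.path(tempdir(), "ml-fixture")
  ml <- generate_scenario(scenario_config("ML", seed = 3), hourly = TRUE)
  write_scenario(ml, dir)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$seed, 3)
  expect_equal(man$regime, "ML")
  back <- read_mooring_csv(file.path(dir, "hourly", "sal30.csv"))
  expect_identical(back$value, ml$hourly$sal30$value)
  daily <- read.csv(file.path(dir, "daily.csv"))
  expect_equal(nrow(daily), nrow(ml$daily))
  unlink(dir, recursive = TRUE)
})

test_that("hourly channels are valid mooring series spanning the scenario", {
  ml <- generate_scenario(scenario_config("ML", seed = 2), hourly = TRUE)
  expect_s3_class(ml$hourly$temp30, "mooring_series")
  expect_equal(attr(ml$hourly$temp30, "nominal_depth"), 30)
  expect_equal(nrow(ml$hourly$temp30), 730 * 24)
  expect_false(anyNA(ml$hourly$sal55$value))
})

test_that("the full pipeline on hourly channels recovers the regime MLD", {
  ml <- generate_scenario(scenario_config("ML"), noise = FALSE, hourly = TRUE)
  h <- ml$hourly
  sig <- cbind(
    potential_density(h$sal30$value, h$temp30$value),
    potential_density(h$sal55$value, h$temp55$value),
    potential_density(h$sal265$value, h$temp265$value)
  )
  st <- density_stack(h$sal30$time, c(30, 55, 265), sig)
  dm <- daily_mld(hourly_mld_min(st))
  # deep winter mixing: MLD reaches the deepest instrument
  expect_equal(max(dm$mld[dm$date < as.Date("2018-04-01")]), 265)
  # during the ML bloom the 55-m instrument still sits in the mixed layer
  bloom <- dm$date >= as.Date("2018-05-20") & dm$date <= as.Date("2018-06-10")
  expect_true(all(dm$mld[bloom] %in% c(55, 0)))
})
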