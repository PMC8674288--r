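grid_field <- function(lats, lons, dates, conc_fun, u = NULL, v = NULL) {
  cells <- expand.grid(lat = lats, lon = lons)
  conc <- matrix(conc_fun(cells$lat, cells$lon), nrow = nrow(cells),
                 ncol = length(dates))
  ice_field(cells, dates, conc, u = u, v = v)
}

test_that("percent ice days counts strict threshold exceedances", {
  dates <- as.Date("2018-04-01") + 0:9
  cells <- data.frame(lat = c(79, 79.5), lon = c(4, 4))
  conc <- rbind(rep(100, 10),                      # always icy
                c(rep(30, 3), rep(10, 7)))         # 3 of 10 days above 20
  f <- ice_field(cells, dates, conc)
  expect_equal(pct_ice_days(f), c(100, 30))
  conc0 <- matrix(0, 2, 10)
  expect_equal(pct_ice_days(ice_field(cells, dates, conc0)), c(0, 0))
  # no-data cell is missing
  concNA <- conc; concNA[2, ] <- NA
  expect_true(is.na(pct_ice_days(ice_field(cells, dates, concNA))[2]))
  # invariant to day ordering
  perm <- sample(10)
  expect_equal(pct_ice_days(ice_field(cells, dates, conc[, perm])),
               pct_ice_days(f))
})

test_that("distance to the ice edge is signed and flips at the threshold", {
  dates <- as.Date("2018-05-01")
  lats <- seq(78, 81, by = 0.25)
  # ice (60%) north of 79.5, open water south
  f <- grid_field(lats, c(4, 5), dates, function(lat, lon) {
    ifelse(lat > 79.5, 60, 5)
  })
  pt_open <- c(lat = 78.5, lon = 4)
  pt_ice <- c(lat = 80.5, lon = 4)
  d_open <- distance_to_ice_edge(f, dates, pt_open)
  d_ice <- distance_to_ice_edge(f, dates, pt_ice)
  expect_gt(d_open, 0)
  expect_lt(d_ice, 0)
  # brute-force distance check from the open-water point to nearest icy cell
  icy <- f$cells[f$conc[, 1] > 20, ]
  d_bf <- min(geosphere::distHaversine(c(4, 78.5),
                                       cbind(icy$lon, icy$lat),
                                       r = 6371000) / 1000)
  expect_equal(d_open, d_bf, tolerance = 1e-9)
  # uniform field: undefined
  funi <- grid_field(lats, c(4, 5), dates, function(lat, lon) 50)
  expect_warning(duni <- distance_to_ice_edge(funi, dates, pt_open), "uniform")
  expect_true(is.na(duni))
})

test_that("gate export reproduces the closed-form uniform case", {
  dates <- as.Date("2018-01-01")
  lats <- seq(81.5, 82.5, by = 0.1)
  lons <- seq(-2, 2, by = 0.25)
  cells <- expand.grid(lat = lats, lon = lons)
  nc <- nrow(cells)
  f <- ice_field(cells, dates, matrix(100, nc, 1),
                 u = matrix(0, nc, 1), v = matrix(-10, nc, 1))
  # zonal gate, west to east: southward drift is positive export
  gate <- data.frame(lat = c(82, 82), lon = c(-1, 1))
  gate_len <- geosphere::distHaversine(c(-1, 82), c(1, 82), r = 6371000) / 1000
  out <- ice_area_export(f, gate)
  expect_equal(as.numeric(out), 10 * 1 * gate_len, tolerance = 1e-9)
  # linear in concentration and drift
  f50 <- ice_field(cells, dates, matrix(50, nc, 1),
                   u = matrix(0, nc, 1), v = matrix(-10, nc, 1))
  expect_equal(as.numeric(ice_area_export(f50, gate)), as.numeric(out) / 2,
               tolerance = 1e-9)
  f2v <- ice_field(cells, dates, matrix(100, nc, 1),
                   u = matrix(0, nc, 1), v = matrix(-20, nc, 1))
  expect_equal(as.numeric(ice_area_export(f2v, gate)), 2 * as.numeric(out),
               tolerance = 1e-9)
  # zero concentration contributes nothing
  f0 <- ice_field(cells, dates, matrix(0, nc, 1),
                  u = matrix(5, nc, 1), v = matrix(-10, nc, 1))
  expect_equal(as.numeric(ice_area_export(f0, gate)), 0)
})

test_that("gate export equals the brute-force per-cell oracle", {
  set.seed(31)
  dates <- as.Date("2018-01-01") + 0:2
  cells <- expand.grid(lat = seq(81.6, 82.4, by = 0.2),
                       lon = seq(-1, 1, by = 0.5))
  nc <- nrow(cells)
  f <- ice_field(cells, dates,
                 conc = matrix(runif(nc * 3, 0, 100), nc, 3),
                 u = matrix(rnorm(nc * 3, 0, 5), nc, 3),
                 v = matrix(rnorm(nc * 3, -8, 5), nc, 3))
  gate <- data.frame(lat = c(82, 82, 81.8), lon = c(-0.8, 0.3, 0.9))
  got <- as.numeric(ice_area_export(f, gate, step_km = 10))
  want <- oracle_gate_export(f, gate, step_km = 10)
  expect_equal(got, want, tolerance = 1e-9)
})
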