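calm <- list(u10 = 0, v10 = 0, q_nonpen = 0, q_sw = 0, emp = 0)

test_that("idealized initial profiles match their construction", {
  p17 <- pwp_profile("P17", dz = 1)
  # cell centres: interpolate to the quoted depths
  s_at <- function(p, z) approx(p$z, p$S, xout = z)$y
  expect_equal(s_at(p17, 0.5), 30.5 + 4.5 / 50 * 0.5, tolerance = 1e-9)
  expect_equal(s_at(p17, 50), 35, tolerance = 1e-3)
  expect_equal(s_at(p17, 200), 35.1, tolerance = 1e-3)
  expect_true(all(p17$T == 2))
  p18 <- pwp_profile("P18", dz = 1)
  expect_equal(s_at(p18, 0.5), 34.8 + 0.2 / 50 * 0.5, tolerance = 1e-9)
  expect_equal(s_at(p18, 25), 34.9, tolerance = 1e-3)
  # identical below 50 m
  deep <- p17$z > 50
  expect_equal(p17$S[deep], p18$S[deep])
  expect_error(pwp_profile("P99"), "arg")
})

test_that("zero forcing leaves a stable profile unchanged", {
  p <- pwp_profile("P17")
  out <- pwp_step(p, calm)
  expect_equal(out$T, p$T)
  expect_equal(out$S, p$S)
  expect_equal(out$U, p$U)  # no momentum to rotate
  expect_error(pwp_step(p, list(u10 = NaN, v10 = 0, q_nonpen = 0,
                                q_sw = 0, emp = 0)), "non-finite")
})

test_that("pure cooling of an unstratified column obeys the heat budget", {
  p <- pwp_profile("P17")
  p$S <- rep(35, length(p$S))  # unstratified
  prm <- pwp_params()
  q <- -200
  out <- p
  for (i in 1:4) out <- pwp_step(out, list(u10 = 0, v10 = 0, q_nonpen = q,
                                           q_sw = 0, emp = 0), dt = 900,
                                 params = prm)
  dheat <- sum(prm$rho0 * prm$cp * (out$T - p$T) * p$dz)
  expect_equal(dheat, q * 4 * 900, tolerance = 1e-6)
  # cooling of a uniform column stays uniform (convectively mixed)
  expect_lt(diff(range(out$T)), 1e-9)
})

test_that("destabilizing surface buoyancy deepens the mixed layer monotonically", {
  p <- pwp_profile("P18")
  mlds <- numeric(12)
  for (i in 1:12) {
    for (j in 1:24) {
      p <- pwp_step(p, list(u10 = 0, v10 = 0, q_nonpen = -400, q_sw = 0,
                            emp = 0), dt = 900)
    }
    mlds[i] <- moorbloom:::pwp_mld(p)
  }
  expect_true(all(diff(mlds) >= 0))
  expect_gt(mlds[12], mlds[1])
})

test_that("short runs conserve heat and salt and keep static stability", {
  f <- generate_forcing("ML", span = c("2018-05-15", "2018-05-30"), seed = 5)
  for (id in c("P17", "P18")) {
    r <- pwp_run(pwp_profile(id), f, days = 10)
    heat_err <- max(abs((r$heat - r$heat[1]) - (r$heat_in - r$heat_in[1])))
    expect_lt(heat_err, 1e-3 * max(abs(r$heat_in)))
    salt_err <- max(abs((r$salt - r$salt[1]) - (r$salt_in - r$salt_in[1])))
    expect_lt(salt_err, 1e-3 * max(abs(r$salt_in)) + 1e-9)
    sig <- potential_density(r$final$S, r$final$T, 0)
    expect_true(all(diff(sig) > -1e-8))
  }
})

test_that("the meltwater profile keeps a shallower mixed layer than P18", {
  f <- generate_forcing("ML", span = c("2018-05-15", "2018-06-05"), seed = 6)
  r17 <- pwp_run(pwp_profile("P17"), f, days = 12)
  r18 <- pwp_run(pwp_profile("P18"), f, days = 12)
  expect_true(all(r18$mld >= r17$mld))
  expect_lt(max(r17$mld), 20)
})

test_that("halving the grid spacing changes the final MLD by < 2 m", {
  f <- generate_forcing("ML", span = c("2018-05-15", "2018-05-25"), seed = 7,
                        noise = FALSE)
  r1 <- pwp_run(pwp_profile("P18", dz = 1), f, days = 6)
  r2 <- pwp_run(pwp_profile("P18", dz = 0.5), f, days = 6)
  expect_lt(abs(tail(r1$mld, 1) - tail(r2$mld, 1)), 2)
})
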