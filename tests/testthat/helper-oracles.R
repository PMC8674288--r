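# Independent brute-force oracles used to cross-check the vectorized
# implementations on small random inputs.

# minimum-MLD estimator by explicit per-time-step enumeration
oracle_mld <- function(time, depths, sigma, threshold = 0.05,
                       offset_correct = TRUE) {
  nlower <- length(depths) - 1
  offs <- numeric(nlower)
  if (offset_correct) {
    for (j in seq_len(nlower)) {
      offs[j] <- quantile(sigma[, j + 1] - sigma[, 1], 0.005,
                          na.rm = TRUE, names = FALSE)
    }
  }
  out <- numeric(length(time))
  for (i in seq_along(time)) {
    if (is.na(sigma[i, 1])) {
      out[i] <- NA_real_
      next
    }
    best <- 0
    for (j in seq_len(nlower)) {
      ds <- sigma[i, j + 1] - sigma[i, 1] - offs[j]
      if (!is.na(ds) && ds < threshold) best <- max(best, depths[j + 1])
    }
    out[i] <- best
  }
  out
}

# gate area export by explicit loops over days and sub-segments
oracle_gate_export <- function(field, gate, step_km = 25) {
  gc_km <- function(lon1, lat1, lon2, lat2) {
    geosphere::distHaversine(c(lon1, lat1), c(lon2, lat2), r = 6371000) / 1000
  }
  total <- 0
  for (j in seq_along(field$dates)) {
    for (s in seq_len(nrow(gate) - 1)) {
      p1 <- gate[s, ]; p2 <- gate[s + 1, ]
      seg_len <- gc_km(p1$lon, p1$lat, p2$lon, p2$lat)
      nsub <- max(1, ceiling(seg_len / step_km))
      latm <- (p1$lat + p2$lat) / 2
      dx <- (p2$lon - p1$lon) * cos(latm * pi / 180)
      dy <- p2$lat - p1$lat
      nrm <- c(dy, -dx) / sqrt(dx^2 + dy^2)
      for (kk in seq_len(nsub)) {
        fr <- (kk - 0.5) / nsub
        latp <- p1$lat + fr * (p2$lat - p1$lat)
        lonp <- p1$lon + fr * (p2$lon - p1$lon)
        dd <- sapply(seq_len(nrow(field$cells)), function(i) {
          gc_km(lonp, latp, field$cells$lon[i], field$cells$lat[i])
        })
        ic <- which.min(dd)
        u <- field$u[ic, j]; v <- field$v[ic, j]; cc <- field$conc[ic, j] / 100
        if (anyNA(c(u, v, cc))) next
        total <- total + (u * nrm[1] + v * nrm[2]) * cc * (seg_len / nsub)
      }
    }
  }
  total
}

# amplitude response of the package's zero-phase lowpass on a pure sinusoid
sinusoid_attenuation <- function(period_days, cutoff_days = 5, n_days = 120) {
  tm <- as.POSIXct("2018-01-01", tz = "UTC") + 3600 * (0:(n_days * 24 - 1))
  t_d <- as.numeric(tm - tm[1], units = "days")
  ms <- mooring_series(tm, sin(2 * pi * t_d / period_days),
                       variable = "x", units = "1", nominal_depth = 30)
  out <- lowpass_filter(ms, cutoff_days = cutoff_days)
  # measure away from the (padded) edges
  core <- seq(15 * 24, (n_days - 15) * 24)
  max(abs(out$value[core]))
}

make_random_stack <- function(nt = 24, depths = c(30, 55, 120, 265),
                              rng_sd = 0.08) {
  base <- 27 + cumsum(c(0, abs(rnorm(length(depths) - 1, 0.03, 0.05))))
  sigma <- t(replicate(nt, base + rnorm(length(depths), 0, rng_sd)))
  density_stack(as.POSIXct("2018-01-01", tz = "UTC") + 3600 * (0:(nt - 1)),
                depths, sigma)
}
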