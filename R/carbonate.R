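#' Carbonate system: alkalinity, DIC and bloom carbon takeup
#'
#' The solver uses a fixed set of equilibrium constants suitable for cold,
#' salinity 30-35 surface waters, all on the total hydrogen-ion scale:
#' CO2 solubility K0 from Weiss (1974), carbonic acid K1/K2 from Lueker et
#' al. (2000), borate KB from Dickson (1990), water KW and the phosphate and
#' silicate constants from Millero (1995), total borate from Uppstrom.
#' Nutrient alkalinity uses the fixed phosphate (0.5 umol/l) and silicate
#' (5 umol/l) concentrations typical of the region unless overridden.
#'
#' @name carbonate
NULL

#' Alkalinity from salinity
#'
#' Regional linear relationship `Alk = 736 + 45.2 * S` (umol/kg).
#'
#' @param salinity practical salinity in [0, 42].
#' @return total alkalinity, umol kg-1.
#' @export
alkalinity_from_salinity <- function(salinity) {
  if (any(salinity < 0 | salinity > 42, na.rm = TRUE)) {
    stop("salinity out of range [0, 42]")
  }
  736 + 45.2 * salinity
}

# equilibrium constants at (T degC, S), total scale, mol/kg units
carbonate_constants <- function(temperature, salinity) {
  T <- temperature + 273.15
  S <- salinity
  lnk0 <- -60.2409 + 93.4517 * (100 / T) + 23.3585 * log(T / 100) +
    S * (0.023517 - 0.023656 * (T / 100) + 0.0047036 * (T / 100)^2)
  pk1 <- 3633.86 / T - 61.2172 + 9.6777 * log(T) - 0.011555 * S + 0.0001152 * S^2
  pk2 <- 471.78 / T + 25.929 - 3.16967 * log(T) - 0.01781 * S + 0.0001122 * S^2
  lnkb <- (-8966.90 - 2890.53 * sqrt(S) - 77.942 * S + 1.728 * S^1.5 -
             0.0996 * S^2) / T +
    148.0248 + 137.1942 * sqrt(S) + 1.62142 * S -
    (24.4344 + 25.085 * sqrt(S) + 0.2474 * S) * log(T) + 0.053105 * sqrt(S) * T
  lnkw <- 148.9802 - 13847.26 / T - 23.6521 * log(T) +
    (118.67 / T - 5.977 + 1.0495 * log(T)) * sqrt(S) - 0.01615 * S
  lnkp1 <- -4576.752 / T + 115.525 - 18.453 * log(T) +
    (-106.736 / T + 0.69171) * sqrt(S) + (-0.65643 / T - 0.01844) * S
  lnkp2 <- -8814.715 / T + 172.0883 - 27.927 * log(T) +
    (-160.340 / T + 1.3566) * sqrt(S) + (0.37335 / T - 0.05778) * S
  lnkp3 <- -3070.75 / T - 18.141 +
    (17.27039 / T + 2.81197) * sqrt(S) + (-44.99486 / T - 0.09984) * S
  I <- 19.924 * S / (1000 - 1.005 * S)
  lnksi <- -8904.2 / T + 117.385 - 19.334 * log(T) +
    (-458.79 / T + 3.5913) * sqrt(I) + (188.74 / T - 1.5998) * I +
    (-12.1652 / T + 0.07871) * I^2 + log(1 - 0.001005 * S)
  list(k0 = exp(lnk0), k1 = 10^(-pk1), k2 = 10^(-pk2), kb = exp(lnkb),
       kw = exp(lnkw), kp1 = exp(lnkp1), kp2 = exp(lnkp2), kp3 = exp(lnkp3),
       ksi = exp(lnksi), bt = 0.0004157 * S / 35)
}

# alkalinity contributions other than carbonate, mol/kg, at [H+] h
minor_alkalinity <- function(h, k, pt, sit) {
  boh4 <- k$bt * k$kb / (k$kb + h)
  oh <- k$kw / h
  pden <- h^3 + k$kp1 * h^2 + k$kp1 * k$kp2 * h + k$kp1 * k$kp2 * k$kp3
  h3po4 <- pt * h^3 / pden
  hpo4 <- pt * k$kp1 * k$kp2 * h / pden
  po4 <- pt * k$kp1 * k$kp2 * k$kp3 / pden
  sioh3 <- sit * k$ksi / (k$ksi + h)
  boh4 + oh - h + hpo4 + 2 * po4 - h3po4 + sioh3
}

# umol/l -> mol/kg using surface density
per_l_to_per_kg <- function(x_umol_l, salinity, temperature) {
  x_umol_l / (seawater_density(salinity, temperature, 0) / 1000) * 1e-6
}

#' Dissolved inorganic carbon from pCO2 and alkalinity
#'
#' Solves the carbonate system for DIC given pCO2, total alkalinity,
#' temperature, salinity and the (fixed) nutrient concentrations. With
#' pCO2 known, `[CO2*] = K0 pCO2` fixes the carbonate alkalinity as a
#' function of `[H+]` alone; the total-alkalinity equation is then solved
#' for `[H+]` by root bracketing and
#' `DIC = [CO2*](1 + K1/[H+] + K1 K2/[H+]^2)`.
#'
#' @param pco2 CO2 partial pressure, uatm (> 0).
#' @param alkalinity total alkalinity, umol kg-1 (e.g. from
#'   [alkalinity_from_salinity()]).
#' @param temperature degC.
#' @param salinity practical salinity.
#' @param phosphate,silicate nutrient concentrations, umol l-1
#'   (defaults 0.5 and 5).
#' @return DIC, umol kg-1 (monotonically increasing in pCO2 at fixed
#'   alkalinity, temperature and salinity).
#' @export
dic_from_pco2 <- function(pco2, alkalinity, temperature, salinity,
                          phosphate = 0.5, silicate = 5) {
  if (any(pco2 <= 0, na.rm = TRUE)) stop("`pco2` must be > 0")
  n <- max(length(pco2), length(alkalinity), length(temperature),
           length(salinity))
  pco2 <- rep_len(pco2, n); alkalinity <- rep_len(alkalinity, n)
  temperature <- rep_len(temperature, n); salinity <- rep_len(salinity, n)
  out <- numeric(n)
  for (i in seq_len(n)) {
    if (anyNA(c(pco2[i], alkalinity[i], temperature[i], salinity[i]))) {
      out[i] <- NA_real_
      next
    }
    k <- carbonate_constants(temperature[i], salinity[i])
    pt <- per_l_to_per_kg(phosphate, salinity[i], temperature[i])
    sit <- per_l_to_per_kg(silicate, salinity[i], temperature[i])
    co2 <- k$k0 * pco2[i] * 1e-6
    ta <- alkalinity[i] * 1e-6
    f <- function(h) {
      co2 * (k$k1 / h + 2 * k$k1 * k$k2 / h^2) +
        minor_alkalinity(h, k, pt, sit) - ta
    }
    root <- tryCatch(
      stats::uniroot(f, interval = c(1e-12, 1e-4), tol = 1e-18),
      error = function(e) stop("carbonate solver did not converge: pCO2=",
                               pco2[i], " uatm, Alk=", alkalinity[i],
                               " umol/kg (", conditionMessage(e), ")")
    )
    h <- root$root
    out[i] <- co2 * (1 + k$k1 / h + k$k1 * k$k2 / h^2) * 1e6
  }
  out
}

#' pCO2 from DIC and alkalinity
#'
#' Inverse of [dic_from_pco2()]: solves the total-alkalinity equation for
#' `[H+]` with the carbonate species expressed through DIC, then converts
#' `[CO2*]` back to partial pressure with the solubility K0.
#'
#' @param dic DIC, umol kg-1.
#' @inheritParams dic_from_pco2
#' @return pCO2, uatm.
#' @export
pco2_from_dic <- function(dic, alkalinity, temperature, salinity,
                          phosphate = 0.5, silicate = 5) {
  n <- max(length(dic), length(alkalinity), length(temperature),
           length(salinity))
  dic <- rep_len(dic, n); alkalinity <- rep_len(alkalinity, n)
  temperature <- rep_len(temperature, n); salinity <- rep_len(salinity, n)
  out <- numeric(n)
  for (i in seq_len(n)) {
    if (anyNA(c(dic[i], alkalinity[i], temperature[i], salinity[i]))) {
      out[i] <- NA_real_
      next
    }
    k <- carbonate_constants(temperature[i], salinity[i])
    pt <- per_l_to_per_kg(phosphate, salinity[i], temperature[i])
    sit <- per_l_to_per_kg(silicate, salinity[i], temperature[i])
    ct <- dic[i] * 1e-6
    ta <- alkalinity[i] * 1e-6
    f <- function(h) {
      den <- h^2 + k$k1 * h + k$k1 * k$k2
      ct * (k$k1 * h + 2 * k$k1 * k$k2) / den +
        minor_alkalinity(h, k, pt, sit) - ta
    }
    h <- stats::uniroot(f, interval = c(1e-12, 1e-4), tol = 1e-18)$root
    co2 <- ct * h^2 / (h^2 + k$k1 * h + k$k1 * k$k2)
    out[i] <- co2 / k$k0 * 1e6
  }
  out
}

#' Bloom carbon takeup from the pCO2 record
#'
#' The carbon takeup of a bloom is the change in DIC between the beginning
#' of the bloom and the time the pCO2 minimum is reached, with DIC computed
#' from pCO2 and salinity-derived alkalinity at the measured temperature and
#' salinity. Positive values indicate a drawdown.
#'
#' @param time timestamps (Date or POSIXct).
#' @param pco2 pCO2 series, uatm.
#' @param salinity,temperature coincident hydrography series.
#' @param bloom_start start of the bloom (within the series).
#' @param ... passed to [dic_from_pco2()] (nutrient concentrations).
#' @return list with `ddic` (umol kg-1), `t_start`, `t_min` (time of the
#'   post-onset pCO2 minimum) and `pco2_drawdown` (uatm).
#' @export
carbon_takeup <- function(time, pco2, salinity, temperature, bloom_start, ...) {
  time <- as_utc(time)
  bloom_start <- as_utc(bloom_start)
  i0 <- which(time >= bloom_start)[1]
  if (is.na(i0)) stop("`bloom_start` is after the end of the series")
  post <- seq(i0, length(time))
  if (all(is.na(pco2[post]))) stop("no pCO2 data after `bloom_start`")
  imin <- post[which.min(pco2[post])]
  dic0 <- dic_from_pco2(pco2[i0], alkalinity_from_salinity(salinity[i0]),
                        temperature[i0], salinity[i0], ...)
  dic1 <- dic_from_pco2(pco2[imin], alkalinity_from_salinity(salinity[imin]),
                        temperature[imin], salinity[imin], ...)
  list(ddic = dic0 - dic1, t_start = time[i0], t_min = time[imin],
       pco2_drawdown = pco2[i0] - pco2[imin])
}

#' Constant pCO2 bias correction over a deployment window
#'
#' Subtracts a constant offset (e.g. the ~130 uatm high bias identified for
#' one deployment) from the pCO2 record, restricted to the given window;
#' samples outside the window are unchanged.
#'
#' @param series a [mooring_series()] of pCO2.
#' @param offset bias to subtract, uatm.
#' @param window optional length-2 vector of POSIXct/Date limits; default is
#'   the whole series.
#' @return the corrected series.
#' @export
apply_pco2_bias <- function(series, offset, window = NULL) {
  stopifnot(inherits(series, "mooring_series"))
  stopifnot_scalar(offset)
  sel <- rep(TRUE, nrow(series))
  if (!is.null(window)) {
    w <- as_utc(window)
    sel <- series$time >= w[1] & series$time <= w[2]
  }
  series$value[sel] <- series$value[sel] - offset
  series
}
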