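#' Seawater equation of state (EOS-80)
#'
#' In-situ density of seawater from practical salinity, in-situ temperature
#' (ITS-68 scale differences are negligible at sensor accuracy) and pressure,
#' using the UNESCO 1983 international equation of state. This matches the
#' classic Seawater-toolbox route used for moored CTD processing.
#'
#' @param salinity practical salinity (dimensionless), 0-42.
#' @param temperature in-situ temperature, degC.
#' @param pressure sea pressure, dbar (default 0).
#' @return density, kg m-3.
#' @export
seawater_density <- function(salinity, temperature, pressure = 0) {
  if (any(!is.finite(salinity)) || any(salinity < 0 | salinity > 42)) {
    stop("salinity out of range [0, 42]")
  }
  if (any(!is.finite(temperature)) || any(temperature < -4 | temperature > 45)) {
    stop("temperature out of range [-4, 45] degC")
  }
  T <- temperature
  S <- salinity
  # density of reference pure water (SMOW)
  rw <- 999.842594 + 6.793952e-2 * T - 9.095290e-3 * T^2 +
    1.001685e-4 * T^3 - 1.120083e-6 * T^4 + 6.536332e-9 * T^5
  r0 <- rw +
    S * (0.824493 - 4.0899e-3 * T + 7.6438e-5 * T^2 -
           8.2467e-7 * T^3 + 5.3875e-9 * T^4) +
    S^1.5 * (-5.72466e-3 + 1.0227e-4 * T - 1.6546e-6 * T^2) +
    4.8314e-4 * S^2
  p <- pressure / 10  # dbar -> bar
  if (all(p == 0)) return(r0)
  # secant bulk modulus
  kw <- 19652.21 + 148.4206 * T - 2.327105 * T^2 +
    1.360477e-2 * T^3 - 5.155288e-5 * T^4
  k0 <- kw +
    S * (54.6746 - 0.603459 * T + 1.09987e-2 * T^2 - 6.1670e-5 * T^3) +
    S^1.5 * (7.944e-2 + 1.6483e-2 * T - 5.3009e-4 * T^2)
  aw <- 3.239908 + 1.43713e-3 * T + 1.16092e-4 * T^2 - 5.77905e-7 * T^3
  a <- aw + S * (2.2838e-3 - 1.0981e-5 * T - 1.6078e-6 * T^2) +
    1.91075e-4 * S^1.5
  bw <- 8.50935e-5 - 6.12293e-6 * T + 5.2787e-8 * T^2
  b <- bw + S * (-9.9348e-7 + 2.0816e-8 * T + 9.1697e-10 * T^2)
  k <- k0 + a * p + b * p^2
  r0 / (1 - p / k)
}

# adiabatic temperature gradient, K/dbar (Fofonoff & Millard 1983)
adiabatic_lapse <- function(salinity, temperature, pressure) {
  T <- temperature; P <- pressure; ds <- salinity - 35
  3.5803e-5 + 8.5258e-6 * T - 6.836e-8 * T^2 + 6.6228e-10 * T^3 +
    ds * (1.8932e-6 - 4.2393e-8 * T) +
    P * (1.8741e-8 - 6.7795e-10 * T + 8.733e-12 * T^2 - 5.4481e-14 * T^3) +
    ds * P * (-1.1351e-10 + 2.7759e-12 * T) +
    P^2 * (-4.6206e-13 + 1.8676e-14 * T - 2.1687e-16 * T^2)
}

#' Potential temperature (Fofonoff & Millard 1983)
#'
#' Temperature a parcel would have if moved adiabatically to
#' `reference_pressure`, integrated with the standard 4th-order Runge-Kutta
#' scheme over the adiabatic lapse rate.
#'
#' @inheritParams seawater_density
#' @param reference_pressure dbar (default 0).
#' @return potential temperature, degC.
#' @export
potential_temperature <- function(salinity, temperature, pressure,
                                  reference_pressure = 0) {
  s <- salinity; t <- temperature; p <- pressure
  h <- reference_pressure - p
  xk <- h * adiabatic_lapse(s, t, p)
  t <- t + 0.5 * xk
  q <- xk
  p <- p + 0.5 * h
  xk <- h * adiabatic_lapse(s, t, p)
  t <- t + 0.29289322 * (xk - q)
  q <- 0.58578644 * xk + 0.121320344 * q
  xk <- h * adiabatic_lapse(s, t, p)
  t <- t + 1.707106781 * (xk - q)
  q <- 3.414213562 * xk - 4.121320344 * q
  p <- p + 0.5 * h
  xk <- h * adiabatic_lapse(s, t, p)
  t + (xk - 2 * q) / 6
}

#' Potential density
#'
#' Density of a parcel moved adiabatically to the reference pressure,
#' from the EOS-80 equation of state.
#'
#' @inheritParams potential_temperature
#' @return potential density, kg m-3 (not the sigma anomaly).
#' @examples
#' potential_density(35, 2, 0)  # ~1027.97 kg m-3
#' @export
potential_density <- function(salinity, temperature, pressure = 0,
                              reference_pressure = 0) {
  theta <- potential_temperature(salinity, temperature, pressure,
                                 reference_pressure)
  seawater_density(salinity, theta, reference_pressure)
}

# thermal expansion (1/degC) and haline contraction (1/psu) coefficients,
# centred finite differences of potential density
alpha_beta <- function(salinity, temperature, pressure = 0) {
  dT <- 1e-3; dS <- 1e-3
  rho <- potential_density(salinity, temperature, pressure)
  drdT <- (potential_density(salinity, temperature + dT, pressure) -
             potential_density(salinity, temperature - dT, pressure)) / (2 * dT)
  drdS <- (potential_density(salinity + dS, temperature, pressure) -
             potential_density(salinity - dS, temperature, pressure)) / (2 * dS)
  list(alpha = -drdT / rho, beta = drdS / rho, rho = rho)
}

#' Buoyancy frequency between two moored sensors
#'
#' Two-point estimate of the stratification between an upper and a lower
#' temperature/salinity recorder,
#' \deqn{N^2 = -\frac{g}{\rho_0}\frac{\Delta\rho}{\Delta z},}
#' with the potential-density difference taken over the sensor separation
#' `dz`. The thermal and haline contributions are
#' \deqn{N_T^2 = g\,\alpha\,\Delta T/\Delta z, \qquad
#'       N_S^2 = -g\,\beta\,\Delta S/\Delta z,}
#' with the expansion/contraction coefficients evaluated at the mean
#' temperature and salinity of the two sensors. Stable stratification gives
#' `n2 > 0`.
#'
#' @param upper,lower lists with `temperature` (degC), `salinity` and
#'   `pressure` (dbar); `upper` is the shallower sensor.
#' @param dz vertical sensor separation, m (> 0).
#' @param g gravitational acceleration, m s-2.
#' @return list of class `"stratification"` with `n2`, `n2_t`, `n2_s` (s-2),
#'   `dz`, `rho0`, `alpha`, `beta`, `g`.
#' @examples
#' buoyancy_frequency(
#'   upper = list(temperature = 2, salinity = 34.67, pressure = 30),
#'   lower = list(temperature = 2, salinity = 35.00, pressure = 55),
#'   dz = 25
#' )$n2  # ~1e-4 s-2
#' @export
buoyancy_frequency <- function(upper, lower, dz, g = 9.81) {
  if (!all(c("temperature", "salinity") %in% names(upper)) ||
      !all(c("temperature", "salinity") %in% names(lower))) {
    stop("`upper` and `lower` need `temperature` and `salinity`")
  }
  if (any(dz <= 0)) stop("`dz` must be > 0")
  pu <- upper$pressure %||% 0
  pl <- lower$pressure %||% 0
  sig_u <- potential_density(upper$salinity, upper$temperature, pu)
  sig_l <- potential_density(lower$salinity, lower$temperature, pl)
  rho0 <- (sig_u + sig_l) / 2
  n2 <- g / rho0 * (sig_l - sig_u) / dz
  ab <- alpha_beta((upper$salinity + lower$salinity) / 2,
                   (upper$temperature + lower$temperature) / 2)
  # differences taken upper minus lower, i.e. along +z (upward)
  n2_t <- g * ab$alpha * (upper$temperature - lower$temperature) / dz
  n2_s <- -g * ab$beta * (upper$salinity - lower$salinity) / dz
  structure(list(n2 = n2, n2_t = n2_t, n2_s = n2_s, dz = dz, rho0 = rho0,
                 alpha = ab$alpha, beta = ab$beta, g = g),
            class = "stratification")
}

#' @export
print.stratification <- function(x, ...) {
  cat(sprintf("N2 = %.3e s-2 (thermal %.3e, haline %.3e) over dz = %g m\n",
              x$n2, x$n2_t, x$n2_s, x$dz))
  invisible(x)
}

#' Oxygen saturation concentration
#'
#' Atmospherically equilibrated oxygen concentration at the water's
#' temperature and salinity. The default formulation is Weiss (1970), the
#' one behind the classic `sw_satO2` routine (ml/l converted to umol/l with
#' 44.6596 umol/ml); Garcia & Gordon (1992, Benson-Krause fit) is available
#' as an alternative.
#'
#' @param salinity practical salinity.
#' @param temperature degC.
#' @param formulation `"weiss"` (default) or `"garcia-gordon"`.
#' @return saturation concentration, umol l-1.
#' @export
oxygen_saturation <- function(salinity, temperature,
                              formulation = c("weiss", "garcia-gordon")) {
  formulation <- match.arg(formulation)
  if (formulation == "weiss") {
    tk <- (temperature + 273.15) / 100
    lnc <- -173.4292 + 249.6339 / tk + 143.3483 * log(tk) - 21.8492 * tk +
      salinity * (-0.033096 + 0.014259 * tk - 0.0017000 * tk^2)
    exp(lnc) * 44.6596  # ml/l -> umol/l
  } else {
    ts <- log((298.15 - temperature) / (273.15 + temperature))
    lnc <- 5.80871 + 3.20291 * ts + 4.17887 * ts^2 + 5.10006 * ts^3 -
      9.86643e-2 * ts^4 + 3.80369 * ts^5 +
      salinity * (-7.01577e-3 - 7.70028e-3 * ts - 1.13864e-2 * ts^2 -
                    9.51519e-3 * ts^3) - 2.75915e-7 * salinity^2
    # umol/kg -> umol/l with surface density
    exp(lnc) * seawater_density(salinity, temperature, 0) / 1000
  }
}

#' Apparent oxygen utilization
#'
#' AOU = saturation concentration minus measured concentration. Negative
#' values indicate net photosynthetic oxygen production.
#'
#' @param o2_measured measured oxygen, umol l-1 (>= 0).
#' @inheritParams oxygen_saturation
#' @return AOU, umol l-1.
#' @export
aou <- function(o2_measured, salinity, temperature,
                formulation = c("weiss", "garcia-gordon")) {
  if (any(o2_measured < 0, na.rm = TRUE)) stop("o2_measured must be >= 0")
  oxygen_saturation(salinity, temperature, formulation) - o2_measured
}

#' Meltwater fraction from a salinity balance
#'
#' Volume fraction of sea-ice meltwater in a surface sample, assuming a
#' two-member mixture of source water (salinity `s_source`) and sea-ice melt
#' (salinity `s_ice`):
#' \deqn{f = (S_{source} - S_{obs})/(S_{source} - S_{ice}).}
#' The defaults (Atlantic Water 35.1, sea ice 8) reproduce a ~1/6 meltwater
#' contribution at an observed surface salinity of 30.5.
#'
#' @param s_obs observed salinity.
#' @param s_source source-water salinity (default 35.1).
#' @param s_ice bulk sea-ice salinity (default 8).
#' @return fraction in [0, 1].
#' @export
meltwater_fraction <- function(s_obs, s_source = 35.1, s_ice = 8) {
  if (any(s_source <= s_ice)) stop("`s_source` must exceed `s_ice`")
  if (any(s_obs > s_source | s_obs < s_ice, na.rm = TRUE)) {
    stop("`s_obs` must lie between `s_ice` and `s_source`")
  }
  (s_source - s_obs) / (s_source - s_ice)
}
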