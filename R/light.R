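#' Light-field parameterizations
#'
#' Constants follow the clear-water treatment used for polar mooring records:
#' diffuse attenuation `kd = 0.02` m-1, shortwave-to-PAR conversion
#' 1 W m-2 = 2.1 umol m-2 s-1, and a sensor detection-limit floor of
#' 10^-1.32 umol m-2 s-1.
#'
#' @name light
NULL

#' PAR detection-limit floor
#'
#' Sensor PAR values below the detection limit are replaced by the constant
#' floor 10^-1.32 umol m-2 s-1 (so that log-scale plots and averages remain
#' defined during the polar night).
#'
#' @param par PAR, umol m-2 s-1.
#' @param floor detection limit (default `10^-1.32`).
#' @return list with `value` (floored PAR) and `flagged` (logical, TRUE where
#'   the floor was applied).
#' @export
floor_detection_limit <- function(par, floor = 10^-1.32) {
  flagged <- !is.na(par) & par < floor
  value <- pmax(par, floor)
  list(value = value, flagged = flagged)
}

#' Convert surface shortwave irradiance to PAR
#'
#' Assumes a constant spectral distribution: 1 W m-2 = 2.1 umol m-2 s-1.
#'
#' @param ssr net surface shortwave radiation, W m-2 (>= 0).
#' @param w_to_par conversion factor (default 2.1).
#' @return PAR, umol m-2 s-1.
#' @export
shortwave_to_par <- function(ssr, w_to_par = 2.1) {
  if (any(ssr < 0, na.rm = TRUE)) stop("`ssr` must be >= 0")
  w_to_par * ssr
}

#' PAR at depth under exponential extinction
#'
#' @param par_surf surface PAR, umol m-2 s-1.
#' @param z depth, m (>= 0).
#' @param kd diffuse attenuation coefficient, m-1 (default 0.02, clear water).
#' @return PAR at depth z.
#' @export
par_at_depth <- function(par_surf, z, kd = 0.02) {
  if (any(z < 0, na.rm = TRUE)) stop("`z` must be >= 0")
  par_surf * exp(-kd * z)
}

#' Mean PAR available in the mixed layer
#'
#' Average light experienced by a phytoplankton cell moved around a
#' clear-water mixed layer of depth MLD:
#' \deqn{PAR_{avail} = \frac{1}{MLD}\int_0^{MLD} PAR_{surf}\,e^{-k_d z}\,dz
#'       = PAR_{surf}\frac{1 - e^{-k_d\,MLD}}{k_d\,MLD},}
#' with the limit `par_surf` as MLD tends to 0.
#'
#' @inheritParams par_at_depth
#' @param mld mixed layer depth, m (>= 0).
#' @return mean mixed-layer PAR, umol m-2 s-1.
#' @export
par_available <- function(par_surf, mld, kd = 0.02) {
  if (any(mld < 0, na.rm = TRUE)) stop("`mld` must be >= 0")
  x <- kd * mld
  fac <- ifelse(x < 1e-8, 1 - x / 2, (1 - exp(-x)) / x)
  par_surf * fac
}

#' Euphotic depth from chlorophyll
#'
#' Power-law parameterization `z_eu = eu_a * chl^eu_b` for Case-1 waters.
#' The default coefficients (34.0, -0.39) are calibrated so that an average
#' chlorophyll concentration of 4 ug/l gives a euphotic depth of ~20 m and
#' 7 ug/l gives ~16 m.
#'
#' @param chl chlorophyll-a concentration, ug l-1 (> 0).
#' @param eu_a scale, m (default 34.0).
#' @param eu_b exponent, dimensionless, < 0 (default -0.39).
#' @return euphotic depth, m.
#' @export
euphotic_depth <- function(chl, eu_a = 34.0, eu_b = -0.39) {
  if (any(chl <= 0, na.rm = TRUE)) stop("`chl` must be > 0")
  if (eu_b >= 0) stop("`eu_b` must be negative")
  eu_a * chl^eu_b
}

#' Day length from the sunrise equation
#'
#' Hours per 24 h that the sun is above the horizon, from the standard
#' sunrise equation with the low-precision solar declination
#' approximation (refraction ignored), clamped to [0, 24] for polar
#' day/night.
#'
#' @param latitude degrees north, in [-90, 90].
#' @param date a `Date` (or coercible).
#' @return day length, hours.
#' @examples
#' day_length(79, as.Date("2018-06-21"))  # 24 (polar day)
#' day_length(79, as.Date("2018-12-21"))  # 0  (polar night)
#' @export
day_length <- function(latitude, date) {
  if (any(abs(latitude) > 90)) stop("`latitude` must be within [-90, 90]")
  doy <- as.integer(format(as.Date(date), "%j"))
  decl <- -23.44 * cos(2 * pi / 365 * (doy + 10)) * pi / 180
  lat <- latitude * pi / 180
  x <- -tan(lat) * tan(decl)
  x <- pmin(1, pmax(-1, x))
  24 * acos(x) / pi
}
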