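#' Normalized mean volume backscattering strength
#'
#' Acoustic proxy for zooplankton/fish biomass: the MVBS record is averaged
#' vertically over a depth layer (linear average of the dB values), averaged
#' to daily values, and normalized by subtracting the per-deployment median
#' of those daily means. The median removal corrects for hardware
#' differences between deployments, so each deployment's normalized series
#' has median zero by construction. A linear-power averaging mode
#' (`db_average = FALSE`) is available for acoustically conventional
#' averaging.
#'
#' @param mvbs data.frame with columns `time`, `depth` (m), `mvbs` (dB) and
#'   optionally `deployment` (id; default: one deployment).
#' @param layer length-2 depth range to average over, m (default `c(50, 100)`).
#' @param db_average average in dB space (default `TRUE`, matching the
#'   deployment-median normalization it feeds).
#' @return data.frame with `date`, `deployment`, `nmvbs` (dB anomaly).
#' @export
normalized_mvbs <- function(mvbs, layer = c(50, 100), db_average = TRUE) {
  need <- c("time", "depth", "mvbs")
  if (!all(need %in% names(mvbs))) stop("`mvbs` needs time, depth, mvbs")
  if (!"deployment" %in% names(mvbs)) mvbs$deployment <- "d1"
  sub <- mvbs[mvbs$depth >= layer[1] & mvbs$depth <= layer[2], ]
  if (!nrow(sub)) stop("no depth bins within the layer")
  vert <- function(x) {
    if (db_average) mean(x, na.rm = TRUE)
    else 10 * log10(mean(10^(x / 10), na.rm = TRUE))
  }
  key_t <- interaction(sub$deployment, as_utc(sub$time), drop = TRUE)
  prof <- tapply(sub$mvbs, key_t, vert)
  meta <- sub[!duplicated(key_t), c("deployment", "time")]
  meta <- meta[order(interaction(meta$deployment, as_utc(meta$time), drop = TRUE)), ]
  df <- data.frame(deployment = meta$deployment,
                   date = as.Date(as_utc(meta$time)),
                   v = as.numeric(prof[levels(key_t)]))
  key_d <- interaction(df$deployment, df$date, drop = TRUE)
  daily <- tapply(df$v, key_d, mean, na.rm = TRUE)
  dmeta <- df[!duplicated(key_d), c("deployment", "date")]
  dmeta <- dmeta[order(interaction(dmeta$deployment, dmeta$date, drop = TRUE)), ]
  out <- data.frame(deployment = dmeta$deployment, date = dmeta$date,
                    nmvbs = as.numeric(daily[levels(key_d)]))
  for (dep in unique(out$deployment)) {
    sel <- out$deployment == dep
    out$nmvbs[sel] <- out$nmvbs[sel] - stats::median(out$nmvbs[sel], na.rm = TRUE)
  }
  out[order(out$deployment, out$date), ]
}

#' Sediment volume flux from water-column trap cups
#'
#' The height of the sedimented layer in a collection cup of 4 cm interior
#' diameter is converted to a volume and normalized by the 0.5 m2 trap
#' collection area and the cup opening duration:
#' `flux = pi * (2 cm)^2 * height / (0.5 m2 * days)` in ml m-2 day-1.
#'
#' @param sediment_height_cm sedimented layer height, cm (>= 0).
#' @param open,close cup opening and closing dates.
#' @param cup_diameter_cm interior cup diameter, cm (default 4).
#' @param collection_area_m2 trap collection area, m2 (default 0.5).
#' @return volume flux, ml m-2 day-1.
#' @export
sediment_volume_flux <- function(sediment_height_cm, open, close,
                                 cup_diameter_cm = 4,
                                 collection_area_m2 = 0.5) {
  if (any(sediment_height_cm < 0, na.rm = TRUE)) stop("height must be >= 0")
  days <- as.numeric(as.Date(close) - as.Date(open))
  if (any(days <= 0)) stop("`close` must be after `open`")
  vol_ml <- pi * (cup_diameter_cm / 2)^2 * sediment_height_cm  # cm3 = ml
  vol_ml / (collection_area_m2 * days)
}

#' POC flux from a bottom-lander sediment trap
#'
#' Measured POC mass per cup, normalized by the sample split factor, the
#' 0.25 m2 collection area and the cup opening duration.
#'
#' @param poc_mass_mg POC mass in the analysed split, mg (>= 0).
#' @param split_factor fraction of the cup analysed (e.g. 0.5 for a half
#'   split).
#' @param open,close cup opening and closing dates.
#' @param collection_area_m2 m2 (default 0.25).
#' @return POC flux, mg C m-2 day-1.
#' @export
lander_poc_flux <- function(poc_mass_mg, split_factor, open, close,
                            collection_area_m2 = 0.25) {
  if (any(poc_mass_mg < 0, na.rm = TRUE)) stop("mass must be >= 0")
  if (any(split_factor <= 0)) stop("`split_factor` must be > 0")
  days <- as.numeric(as.Date(close) - as.Date(open))
  if (any(days <= 0)) stop("`close` must be after `open`")
  poc_mass_mg / split_factor / collection_area_m2 / days
}

#' POC flux from benthic oxygen consumption
#'
#' Converts a sediment oxygen uptake rate to the POC flux reaching the
#' benthos, assuming a respiratory quotient RQ (mol CO2 produced per mol O2
#' consumed; default 1): `flux = o2 * rq * 12.011` mg C m-2 day-1.
#'
#' @param o2_flux_mmol benthic O2 consumption, mmol O2 m-2 day-1 (>= 0).
#' @param rq respiratory quotient (default 1.0).
#' @return POC flux, mg C m-2 day-1.
#' @export
benthic_o2_to_poc <- function(o2_flux_mmol, rq = 1.0) {
  if (any(o2_flux_mmol < 0, na.rm = TRUE)) stop("`o2_flux_mmol` must be >= 0")
  o2_flux_mmol * rq * 12.011
}

#' Detritus coverage from seafloor image box counts
#'
#' Seafloor frame grabs are divided into 100 equal-area boxes and each box
#' is assigned to bare seafloor, fine white (aged) detritus or green (fresh
#' algal) detritus; counts convert directly to percent coverage.
#'
#' @param bare,white,green box counts; must sum to at most 100.
#' @return named numeric vector of percentages.
#' @export
detritus_coverage <- function(bare = 0, white = 0, green = 0) {
  counts <- c(bare = bare, white = white, green = green)
  if (any(counts < 0)) stop("counts must be >= 0")
  if (sum(counts) > 100) stop("counts exceed the 100 image boxes")
  counts
}
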