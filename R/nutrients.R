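#' Nutrient-balance tracers
#'
#' `nstar` is the nitrate excess relative to Redfield phosphorus,
#' `nitrate - 16 * phosphate`; `sistar` is the silicate excess relative to
#' nitrate, `silicate - nitrate`. Both in umol l-1.
#'
#' @param nitrate,phosphate,silicate concentrations, umol l-1 (>= 0).
#' @return tracer value, umol l-1.
#' @export
nstar <- function(nitrate, phosphate) {
  if (any(nitrate < 0 | phosphate < 0, na.rm = TRUE)) {
    stop("concentrations must be >= 0")
  }
  nitrate - 16 * phosphate
}

#' @rdname nstar
#' @export
sistar <- function(silicate, nitrate) {
  if (any(silicate < 0 | nitrate < 0, na.rm = TRUE)) {
    stop("concentrations must be >= 0")
  }
  silicate - nitrate
}

#' SUNA nitrate drift and offset correction
#'
#' The optical nitrate sensor drifts linearly with accumulated lamp time;
#' at the deployment duty cycle this amounts to 2.4 umol l-1 per 365 days.
#' The correction removes `rate * (t - t0)/365 d` plus a constant `offset`
#' determined from in-situ concentrations at the start of the deployment.
#' Small negative corrected values are clipped to 0 and flagged
#' `below_detection`.
#'
#' @param series a [mooring_series()] of raw nitrate, umol l-1.
#' @param rate drift rate, umol l-1 per 365 days (default 2.4).
#' @param offset constant offset, umol l-1 (default 0).
#' @param t0 deployment start; defaults to the first timestamp.
#' @return the corrected series.
#' @export
suna_drift_correct <- function(series, rate = 2.4, offset = 0, t0 = NULL) {
  stopifnot(inherits(series, "mooring_series"))
  t0 <- as_utc(t0 %||% series$time[1])
  el_days <- num_days(series$time, t0)
  v <- series$value - rate * el_days / 365 - offset
  neg <- !is.na(v) & v < 0
  v[neg] <- 0
  series$value <- v
  series$qc_flag[neg & series$qc_flag == "ok"] <- "below_detection"
  series
}

#' Column-integrated standing stock
#'
#' Integrates a uniform concentration over a layer:
#' `conc [umol/l] * thickness [m] * 1e-3` = mol m-2.
#'
#' @param conc concentration, umol l-1 (>= 0).
#' @param thickness layer thickness, m (> 0).
#' @return standing stock, mol m-2.
#' @examples
#' column_stock(12, 50)  # 0.6 mol m-2 of nitrate
#' @export
column_stock <- function(conc, thickness) {
  if (any(conc < 0, na.rm = TRUE)) stop("`conc` must be >= 0")
  if (any(thickness <= 0)) stop("`thickness` must be > 0")
  conc * thickness * 1e-3
}

#' Potential new production from a nitrate stock (Redfield)
#'
#' Converts a column nitrate stock to the carbon production it could
#' support at Redfield stoichiometry: `stock * 106/16 * 12.011` g C m-2.
#'
#' @param nitrate_stock mol NO3 m-2 (>= 0).
#' @param c_to_n Redfield carbon-to-nitrogen ratio (default 106/16).
#' @return potential production, g C m-2.
#' @examples
#' redfield_carbon(0.6)  # ~47.7, i.e. "~50" g C m-2
#' @export
redfield_carbon <- function(nitrate_stock, c_to_n = 106 / 16) {
  if (any(nitrate_stock < 0, na.rm = TRUE)) stop("stock must be >= 0")
  nitrate_stock * c_to_n * 12.011
}

#' Phytoplankton carbon from a chlorophyll stock
#'
#' @param chl_stock column chlorophyll, g Chl m-2 (>= 0).
#' @param ratio carbon-to-chlorophyll mass ratio (default 50; plausible
#'   range roughly 6-60 over a bloom).
#' @return carbon, g C m-2.
#' @export
chl_carbon <- function(chl_stock, ratio = 50) {
  if (any(chl_stock < 0, na.rm = TRUE)) stop("stock must be >= 0")
  chl_stock * ratio
}

#' Read a discrete-sample nutrient table
#'
#' CSV with columns `time` (ISO-8601), `depth` (m) and the four nutrients
#' `nitrate`, `nitrite`, `phosphate`, `silicate` (umol l-1).
#'
#' @param path file path.
#' @return data.frame with parsed UTC times.
#' @export
read_nutrient_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time", "depth", "nitrate", "nitrite", "phosphate", "silicate")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  df$time <- as_utc(df$time)
  df
}

#' Bloom production budget
#'
#' Assembles the three companion production estimates for a bloom: potential
#' new production from the nitrate standing stock (Redfield), carbon takeup
#' from the DIC drawdown integrated over the productive layer, and
#' phytoplankton carbon from the chlorophyll stock.
#'
#' @param nitrate_conc pre-bloom nitrate, umol l-1.
#' @param ddic DIC drawdown, umol kg-1 (from [carbon_takeup()]).
#' @param chl_max maximum chlorophyll concentration, ug l-1.
#' @param thickness productive-layer thickness, m.
#' @param density mean seawater density, kg m-3 (to convert per-kg DIC to
#'   volumetric units; default 1027.5).
#' @param chl_to_c carbon-to-chlorophyll ratio (default 50).
#' @return list with `nitrate_stock` (mol m-2), `carbon_potential`,
#'   `carbon_from_dic`, `carbon_from_chl` (all g C m-2) and
#'   `layer_thickness` (m).
#' @export
bloom_budget <- function(nitrate_conc, ddic, chl_max, thickness,
                         density = 1027.5, chl_to_c = 50) {
  nitrate_stock <- column_stock(nitrate_conc, thickness)
  ddic_umol_l <- ddic * density / 1000
  carbon_from_dic <- column_stock(ddic_umol_l, thickness) * 12.011
  chl_stock_g <- chl_max * 1e-3 * thickness  # ug/l * m -> g/m2 (1 ug/l = 1 mg/m3)
  list(
    nitrate_stock = nitrate_stock,
    carbon_potential = redfield_carbon(nitrate_stock),
    carbon_from_dic = carbon_from_dic,
    carbon_from_chl = chl_carbon(chl_stock_g, chl_to_c),
    layer_thickness = thickness
  )
}
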