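#' Fluorometric chlorophyll with the community bias factor
#'
#' Manufacturer calibrations of ECO-series fluorometers against a
#' mono-culture typically overestimate in-situ chlorophyll; the
#' community-established correction divides the manufacturer-scale value by
#' a bias factor of 2. The factor is exposed because it varies between
#' water masses.
#'
#' @param fluor_chl manufacturer-scale chlorophyll, ug l-1 (>= 0).
#' @param bias bias factor (default 2).
#' @return corrected chlorophyll, ug l-1.
#' @examples
#' fluor_to_chl(14)  # 7 ug/l, a mixed-layer bloom maximum
#' @export
fluor_to_chl <- function(fluor_chl, bias = 2) {
  if (any(fluor_chl < 0, na.rm = TRUE)) stop("`fluor_chl` must be >= 0")
  if (bias <= 0) stop("`bias` must be > 0")
  fluor_chl / bias
}

#' Aggregation flag from optical backscatter bursts
#'
#' Times when any individual 1-s backscatter sample within a burst strictly
#' exceeds 0.002 m-1 sr-1 indicate large, potentially aggregated particles
#' rather than the small-particle background; the flag is raised on the
#' individual-sample rule, not on the burst mean.
#'
#' @param backscatter_samples numeric burst samples, m-1 sr-1 (>= 0).
#' @param threshold exceedance threshold (default 0.002, strict `>`).
#' @return `TRUE` if any sample exceeds the threshold, `FALSE` otherwise,
#'   `NA` for an empty burst.
#' @export
aggregation_flag <- function(backscatter_samples, threshold = 0.002) {
  x <- backscatter_samples[!is.na(backscatter_samples)]
  if (!length(x)) return(NA)
  if (any(x < 0)) stop("backscatter samples must be >= 0")
  any(x > threshold)
}
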