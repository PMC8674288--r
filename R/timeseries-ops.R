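#' Average a sampling burst to one value
#'
#' Moored optical sensors sample short bursts (5, 8 or 10 measurements taken
#' 1 s apart) once per hour. The burst is reduced to a single hourly value by
#' the arithmetic mean of the unmasked samples; the value is stamped at the
#' burst start time by the caller.
#'
#' @param values numeric burst samples.
#' @param qc_flag optional per-sample flags; `"blowdown"`/`"missing"` samples
#'   are excluded from the mean.
#' @return list with `value` (mean of unmasked samples, `NA` if none) and
#'   `qc_flag` (`"ok"` or `"missing"`).
#' @examples
#' burst_average(c(0, 2, 4, 6, 8))$value  # 4
#' @export
burst_average <- function(values, qc_flag = NULL) {
  if (is.null(qc_flag)) qc_flag <- ifelse(is.na(values), "missing", "ok")
  keep <- !is_masked(qc_flag) & !is.na(values)
  if (!any(keep)) {
    return(list(value = NA_real_, qc_flag = "missing"))
  }
  list(value = mean(values[keep]), qc_flag = "ok")
}

#' Flag mooring blow-downs
#'
#' Strong currents intermittently drag moored instruments far below their
#' nominal depth (excursions up to ~200 m). Samples taken while the instrument
#' is more than `threshold_m` below its nominal depth are flagged `"blowdown"`
#' and excluded from all downstream statistics; other flags are unchanged.
#'
#' @param series a [mooring_series()] with an `actual_depth` column.
#' @param threshold_m allowed downward excursion, m (default 10).
#' @return the series with updated `qc_flag`.
#' @export
mask_blowdowns <- function(series, threshold_m = 10) {
  stopifnot(inherits(series, "mooring_series"))
  if (!"actual_depth" %in% names(series)) {
    warning("no `actual_depth` column; blow-down masking skipped")
    return(series)
  }
  excursion <- series$actual_depth - attr(series, "nominal_depth")
  hit <- !is.na(excursion) & excursion > threshold_m
  series$qc_flag[hit] <- "blowdown"
  series
}

# half-power adjustment for an order-n Butterworth applied forward-backward:
# amplitude after filtfilt is (1 + (w/wc)^(2n))^-1, so the half-power
# frequency sits at wc * (sqrt(2)-1)^(1/(2n))
filtfilt_halfpower_factor <- function(order) (sqrt(2) - 1)^(1 / (2 * order))

#' Zero-phase lowpass filter for hourly series
#'
#' Applies an order-4 Butterworth filter forward and backward (zero phase lag)
#' to a regularly sampled hourly series. The design frequency is adjusted so
#' that the half-power point of the combined two-pass response falls at
#' `1/cutoff_days` cycles per day. Edges are padded by reflection before
#' filtering. Gaps up to `max_gap_hours` are linearly interpolated first;
#' longer gaps propagate as missing values in the output. The filter has unit
#' gain at zero frequency, so the series mean is preserved.
#'
#' @param series a [mooring_series()] with regular hourly spacing.
#' @param cutoff_days half-power period, days (default 5).
#' @param max_gap_hours longest gap bridged by linear interpolation (default 6).
#' @param order Butterworth order per pass (default 4).
#' @return the filtered [mooring_series()].
#' @export
lowpass_filter <- function(series, cutoff_days = 5, max_gap_hours = 6,
                           order = 4) {
  stopifnot(inherits(series, "mooring_series"))
  dt_h <- as.numeric(diff(series$time), units = "hours")
  if (any(abs(dt_h - 1) > 1e-6)) stop("series must have regular hourly spacing")
  n <- nrow(series)
  cutoff_samples <- cutoff_days * 24
  if (n < 3 * cutoff_samples) {
    stop("series shorter than 3 filter lengths (", 3 * cutoff_samples,
         " hourly samples)")
  }

  v <- series_values(series)
  bad <- is.na(v)
  long_gap <- rep(FALSE, n)
  if (any(bad)) {
    if (all(bad)) stop("no valid samples to filter")
    r <- rle(bad)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in seq_along(r$lengths)) {
      if (r$values[k] && r$lengths[k] > max_gap_hours) {
        long_gap[starts[k]:ends[k]] <- TRUE
      }
    }
    idx <- which(!bad)
    v <- stats::approx(idx, v[idx], xout = seq_len(n), rule = 2)$y
  }

  wc <- (1 / cutoff_samples) / 0.5 / filtfilt_halfpower_factor(order)
  bf <- signal::butter(order, wc, type = "low")
  pad <- min(n - 1L, 3L * cutoff_samples)
  padded <- c(2 * v[1] - v[(pad + 1):2],   # reflect about the first point
              v,
              2 * v[n] - v[(n - 1):(n - pad)])
  # filter the deviation from the mean so the DC component passes exactly
  v0 <- mean(padded)
  filt <- signal::filtfilt(bf, padded - v0) + v0
  out <- filt[(pad + 1):(pad + n)]
  out[long_gap] <- NA_real_

  res <- series
  res$value <- out
  res$qc_flag <- ifelse(is.na(out), "missing", "ok")
  res
}

#' Daily means of an hourly series
#'
#' Calendar-day (UTC) arithmetic mean over unmasked samples. Days with fewer
#' than `min_samples` valid hourly values are reported missing.
#'
#' @param series a [mooring_series()] with hourly sampling.
#' @param min_samples minimum valid samples per day (default 6).
#' @return data.frame with `date` (Date, UTC), `value` and `n` (valid samples).
#' @export
daily_mean <- function(series, min_samples = 6) {
  stopifnot(inherits(series, "mooring_series"))
  v <- series_values(series)
  day <- as.Date(series$time, tz = "UTC")
  sp <- split(v, day)
  dates <- as.Date(names(sp))
  m <- vapply(sp, function(x) mean(x, na.rm = TRUE), numeric(1))
  n <- vapply(sp, function(x) sum(!is.na(x)), numeric(1))
  m[n < min_samples] <- NA_real_
  m[!is.finite(m)] <- NA_real_
  data.frame(date = dates, value = unname(m), n = unname(as.integer(n)))
}
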