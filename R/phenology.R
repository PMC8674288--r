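#' Bloom onset from the surface heat flux
#'
#' Deep winter mixing stops, and spring stratification (hence the bloom)
#' starts, when the net surface heat flux turns positive (positive values
#' warm the ocean). Because early-season warming can be interrupted
#' intermittently, the onset is the first date from which the flux stays
#' positive for at least `persistence_days` consecutive days.
#'
#' @param date daily dates.
#' @param heat_flux net surface heat flux, W m-2 (positive warms the ocean).
#' @param persistence_days required run of positive days (default 5).
#' @return onset `Date`.
#' @export
detect_bloom_onset <- function(date, heat_flux, persistence_days = 5) {
  date <- as.Date(date)
  pos <- !is.na(heat_flux) & heat_flux > 0
  r <- rle(pos)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  ok <- which(r$values & r$lengths >= persistence_days)
  if (!length(ok)) stop("no date with heat flux positive for ",
                        persistence_days, " consecutive days")
  date[starts[ok[1]]]
}

#' Bloom end from nitrate depletion
#'
#' The bloom crashes when nitrate in the productive layer is depleted: the
#' end is the first (post-onset) date with nitrate below
#' `depletion_threshold`. Blooms that never deplete nitrate (the meltwater
#' regime as seen at 30 m) have no detectable end and return `NA`.
#'
#' @param date daily dates.
#' @param nitrate daily nitrate in the productive layer, umol l-1.
#' @param onset optional onset date; only later dates are considered.
#' @param depletion_threshold umol l-1 (default 1).
#' @return end `Date`, or `NA` if nitrate never falls below the threshold.
#' @export
detect_bloom_end <- function(date, nitrate, onset = NULL,
                             depletion_threshold = 1) {
  date <- as.Date(date)
  sel <- !is.na(nitrate) & nitrate < depletion_threshold
  if (!is.null(onset)) sel <- sel & date >= as.Date(onset)
  if (!any(sel)) return(as.Date(NA))
  date[which(sel)[1]]
}

#' E-folding growth rate of chlorophyll
#'
#' Least-squares slope of `ln(chl)` against time (days) over a window,
#' i.e. the e-folding exponent of the early-bloom biomass increase.
#' Non-positive chlorophyll values are excluded with a warning.
#'
#' @param date dates.
#' @param chl daily chlorophyll, ug l-1.
#' @param window optional length-2 date vector delimiting the fit.
#' @return list with `rate` (day-1), `se` (standard error), `n`.
#' @export
efolding_growth_rate <- function(date, chl, window = NULL) {
  date <- as.Date(date)
  keep <- !is.na(chl)
  if (!is.null(window)) {
    window <- as.Date(window)
    keep <- keep & date >= window[1] & date <= window[2]
  }
  if (any(keep & chl <= 0)) {
    warning("non-positive chlorophyll values excluded from log-linear fit")
    keep <- keep & chl > 0
  }
  if (sum(keep) < 5) stop("need at least 5 positive values in the window")
  x <- as.numeric(date[keep] - date[keep][1])
  y <- log(chl[keep])
  if (stats::var(y) == 0) {
    return(list(rate = 0, se = 0, n = sum(keep)))
  }
  n <- length(x)
  m <- stats::cov(x, y) / stats::var(x)
  b <- mean(y) - m * mean(x)
  ss_res <- sum((y - (m * x + b))^2)
  se <- sqrt(ss_res / (n - 2) / sum((x - mean(x))^2))
  list(rate = m, se = se, n = n)
}

# ordinary least squares y = m x + b with r^2
ols_fit <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 2) return(list(m = NA_real_, b = NA_real_, r2 = NA_real_, n = n))
  m <- stats::cov(x, y) / stats::var(x)
  b <- mean(y) - m * mean(x)
  ss_res <- sum((y - (m * x + b))^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  list(m = m, b = b, r2 = r2, n = n)
}

#' Bloom stoichiometry regressions
#'
#' Ordinary least-squares fits `y = m x + b` between daily averages of the
#' biogeochemical state variables over the bloom window, and again over the
#' post-bloom window: nitrate vs AOU, pCO2 vs AOU, chlorophyll vs AOU,
#' chlorophyll vs nitrate, plus AOU vs nitrate (the oxygen produced per
#' nitrate consumed, ~7 by Redfield-like coupling during the early bloom).
#'
#' @param daily data.frame with columns `date`, `aou`, `nitrate`, `pco2`,
#'   `chl` (daily averages).
#' @param bloom_window length-2 date vector (start, end of bloom).
#' @param post_window optional length-2 date vector for the post-bloom fit.
#' @param min_pairs minimum paired daily values per fit (default 10).
#' @return nested list: `$bloom` and (if requested) `$post`, each a named
#'   list of fits (`m`, `b`, `r2`, `n`) keyed by `"<y>_vs_<x>"`.
#' @export
stoichiometry_regressions <- function(daily, bloom_window, post_window = NULL,
                                      min_pairs = 10) {
  need <- c("date", "aou", "nitrate", "pco2", "chl")
  miss <- setdiff(need, names(daily))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  pairs <- list(
    nitrate_vs_aou = c("aou", "nitrate"),
    pco2_vs_aou = c("aou", "pco2"),
    chl_vs_aou = c("aou", "chl"),
    chl_vs_nitrate = c("nitrate", "chl"),
    aou_vs_nitrate = c("nitrate", "aou")
  )
  fit_window <- function(win) {
    win <- as.Date(win)
    sub <- daily[as.Date(daily$date) >= win[1] & as.Date(daily$date) <= win[2], ]
    out <- lapply(pairs, function(p) {
      f <- ols_fit(sub[[p[1]]], sub[[p[2]]])
      if (f$n < min_pairs) {
        stop("fewer than ", min_pairs, " paired daily values in window")
      }
      f
    })
    out
  }
  res <- list(bloom = fit_window(bloom_window))
  if (!is.null(post_window)) res$post <- fit_window(post_window)
  res
}

#' Stratification regime classification
#'
#' A water column is in the meltwater (MW) regime when the mixed layer is
#' shallow and the surface is strongly freshened (`mld < mld_threshold` and
#' `ds > ds_threshold`, where `ds` is the salinity difference between the
#' surface and 100 m); in the mixed-layer (ML) regime when shallow but not
#' freshened (`ds <= ds_threshold`); and unstratified otherwise
#' (`mld >= mld_threshold`).
#'
#' @param mld mixed layer depth, m.
#' @param ds salinity difference between the surface and 100 m depth,
#'   positive when the surface is fresher.
#' @param mld_threshold m (default 50).
#' @param ds_threshold salinity difference (default 1).
#' @return character vector in `c("MW", "ML", "unstratified")`.
#' @export
classify_regime <- function(mld, ds, mld_threshold = 50, ds_threshold = 1) {
  if (mld_threshold <= 0 || ds_threshold <= 0) {
    stop("thresholds must be > 0")
  }
  out <- ifelse(mld < mld_threshold,
                ifelse(ds > ds_threshold, "MW", "ML"),
                "unstratified")
  out[is.na(mld) | is.na(ds)] <- NA_character_
  out
}

#' Areal coverage per stratification regime
#'
#' Sums cell areas per regime class over a gridded (mld, ds) field; the
#' three classes partition the total area.
#'
#' @param mld,ds per-cell values (see [classify_regime()]).
#' @param area_km2 per-cell areas, km2.
#' @param ... passed to [classify_regime()].
#' @return named numeric vector of km2 for `MW`, `ML`, `unstratified`.
#' @export
regime_area <- function(mld, ds, area_km2, ...) {
  if (length(area_km2) != length(mld)) stop("`area_km2` length mismatch")
  cls <- classify_regime(mld, ds, ...)
  out <- c(MW = 0, ML = 0, unstratified = 0)
  agg <- tapply(area_km2, factor(cls, levels = names(out)), sum)
  out[!is.na(agg)] <- agg[!is.na(agg)]
  out
}

#' Export lag and retention time from flux series
#'
#' For each observation depth, finds the date of the post-onset flux maximum
#' and reports its lag after the bloom onset. The lag at the deepest level
#' is the retention time of the production in the upper ocean.
#'
#' @param onset bloom onset date.
#' @param flux data.frame with columns `date`, `depth` (m) and `flux`.
#' @return data.frame with one row per depth: `depth`, `peak_date`,
#'   `lag_days`, `lag_weeks`, `lag_months` (30.44-day months); attribute
#'   `retention_months` carries the deepest level's lag.
#' @export
export_lag <- function(onset, flux) {
  onset <- as.Date(onset)
  need <- c("date", "depth", "flux")
  if (!all(need %in% names(flux))) stop("`flux` needs date, depth, flux")
  flux$date <- as.Date(flux$date)
  post <- flux[flux$date >= onset & !is.na(flux$flux), ]
  if (!nrow(post)) stop("no flux data at or after the onset")
  depths <- sort(unique(post$depth))
  rows <- lapply(depths, function(d) {
    sub <- post[post$depth == d, ]
    pk <- sub$date[which.max(sub$flux)]
    lag <- as.numeric(pk - onset)
    data.frame(depth = d, peak_date = pk, lag_days = lag,
               lag_weeks = lag / 7, lag_months = lag / DAYS_PER_MONTH)
  })
  out <- do.call(rbind, rows)
  attr(out, "retention_months") <- out$lag_months[which.max(out$depth)]
  out
}

#' Summarize a bloom season from a scenario dataset
#'
#' Runs the phenology chain on a (synthetic or observed) dataset in the
#' layout produced by [generate_scenario()]: onset from the heat flux, end
#' from nitrate depletion, duration in 30.44-day months, early-bloom
#' e-folding growth rate, stoichiometric regressions over the bloom window,
#' regime classification, and export lags per trap depth.
#'
#' @param ds a scenario dataset (see [generate_scenario()]).
#' @param growth_days days after onset used for the growth-rate fit
#'   (default 20).
#' @return list of class `"bloom_summary"`.
#' @export
bloom_summary <- function(ds, growth_days = 20) {
  d <- ds$daily
  # a multi-year record crosses zero every spring; summarize the season the
  # scenario is configured for
  dd <- d[d$date >= as.Date(ds$config$bloom_start) - 120, ]
  onset <- detect_bloom_onset(dd$date, dd$heat_flux)
  end <- detect_bloom_end(d$date, d$nitrate, onset = onset)
  reg_window <- c(onset, if (!is.na(end)) end else as.Date(ds$config$bloom_end))
  duration <- as.numeric(reg_window[2] - onset) / DAYS_PER_MONTH
  gw <- c(onset + 3, onset + 3 + growth_days)
  growth <- tryCatch(
    efolding_growth_rate(d$date, d$chl, window = gw),
    error = function(e) list(rate = NA_real_, se = NA_real_, n = 0)
  )
  slopes <- tryCatch(
    stoichiometry_regressions(d, bloom_window = reg_window),
    error = function(e) NULL
  )
  regime <- {
    sel <- d$date >= reg_window[1] & d$date <= reg_window[2]
    cls <- classify_regime(d$mld[sel], d$ds[sel])
    names(which.max(table(cls)))
  }
  lags <- export_lag(onset, ds$traps)
  structure(list(
    bloom_start = onset, bloom_end = end, duration_months = duration,
    growth_rate = growth$rate, slopes = slopes, regime = regime,
    export = lags, retention_months = attr(lags, "retention_months")
  ), class = "bloom_summary")
}

#' @export
print.bloom_summary <- function(x, ...) {
  cat("Bloom summary\n")
  cat(sprintf("  regime:          %s\n", x$regime))
  cat(sprintf("  start:           %s\n", format(x$bloom_start)))
  cat(sprintf("  end:             %s\n",
              if (is.na(x$bloom_end)) "not detected (no nitrate depletion)"
              else format(x$bloom_end)))
  cat(sprintf("  duration:        %.1f months\n", x$duration_months))
  cat(sprintf("  growth rate:     %.2f day-1\n", x$growth_rate))
  if (!is.null(x$slopes)) {
    s <- x$slopes$bloom
    cat(sprintf("  O2:NO3 slope:    %.2f (r2 %.2f)\n",
                s$aou_vs_nitrate$m, s$aou_vs_nitrate$r2))
    cat(sprintf("  chl:NO3 slope:   %.2f (r2 %.2f)\n",
                s$chl_vs_nitrate$m, s$chl_vs_nitrate$r2))
  }
  cat(sprintf("  retention:       %.1f months (deepest trap)\n",
              x$retention_months))
  invisible(x)
}
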