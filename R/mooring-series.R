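#' Moored sensor time series
#'
#' A `mooring_series` holds the timestamped values of one variable measured by
#' one instrument at one nominal depth, together with quality-control flags and
#' (optionally) the instrument's actual depth from its pressure record. It is a
#' plain data.frame with columns `time` (POSIXct, UTC), `value`, `qc_flag`
#' (one of `"ok"`, `"below_detection"`, `"blowdown"`, `"missing"`) and
#' optionally `actual_depth` (m), plus attributes `variable`, `units` and
#' `nominal_depth`.
#'
#' Samples flagged `"blowdown"` or `"missing"` are masked: they never enter
#' any downstream average or fit.
#'
#' @param time POSIXct (or coercible) timestamps, UTC, strictly increasing.
#' @param value numeric measurements; `NA` entries are flagged `"missing"`.
#' @param variable short variable name, e.g. `"salinity"`.
#' @param units unit string; must be non-empty (use `"1"` for dimensionless).
#' @param nominal_depth nominal instrument depth, m positive down.
#' @param actual_depth optional actual depth from pressure, m.
#' @param qc_flag optional character flags; defaults to `"ok"`/`"missing"`.
#'
#' @return A data.frame of class `"mooring_series"`.
#' @examples
#' ms <- mooring_series(
#'   time = as.POSIXct("2018-05-01", tz = "UTC") + 3600 * (0:5),
#'   value = c(34.9, 34.9, NA, 35.0, 35.0, 35.0),
#'   variable = "salinity", units = "1", nominal_depth = 30
#' )
#' ms
#' @export
mooring_series <- function(time, value, variable = "value", units = "1",
                           nominal_depth = NA_real_, actual_depth = NULL,
                           qc_flag = NULL) {
  time <- as_utc(time)
  if (length(time) != length(value)) stop("`time` and `value` lengths differ")
  if (anyNA(time)) stop("`time` must not contain NA")
  if (is.unsorted(time, strictly = TRUE)) {
    stop("`time` must be strictly increasing")
  }
  if (!is.character(units) || length(units) != 1L || !nzchar(units)) {
    stop("`units` must be a non-empty string")
  }
  value <- as.numeric(value)
  if (is.null(qc_flag)) {
    qc_flag <- ifelse(is.na(value), "missing", "ok")
  } else {
    qc_flag <- as.character(qc_flag)
    if (!all(qc_flag %in% QC_LEVELS)) {
      stop("qc_flag entries must be one of: ", paste(QC_LEVELS, collapse = ", "))
    }
    qc_flag[is.na(value) & !is_masked(qc_flag)] <- "missing"
  }
  df <- data.frame(time = time, value = value, qc_flag = qc_flag,
                   stringsAsFactors = FALSE)
  if (!is.null(actual_depth)) {
    if (length(actual_depth) != length(value)) {
      stop("`actual_depth` length must match `value`")
    }
    df$actual_depth <- as.numeric(actual_depth)
  }
  structure(df,
            class = c("mooring_series", "data.frame"),
            variable = variable, units = units,
            nominal_depth = as.numeric(nominal_depth))
}

#' @export
print.mooring_series <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("<mooring_series> %s [%s] at %s m, %d samples\n",
              attr(x, "variable"), attr(x, "units"),
              format(attr(x, "nominal_depth")), n))
  if (n > 0) {
    cat(sprintf("  %s .. %s UTC; %d masked\n",
                format(x$time[1]), format(x$time[n]),
                sum(is_masked(x$qc_flag))))
    print.data.frame(utils::head(as.data.frame(x), 4))
    if (n > 4) cat("  ...\n")
  }
  invisible(x)
}

#' Values of a mooring series with masked samples set to NA
#'
#' @param x a [mooring_series()].
#' @return numeric vector, masked (`blowdown`/`missing`) entries `NA`.
#' @export
series_values <- function(x) {
  v <- x$value
  v[is_masked(x$qc_flag)] <- NA_real_
  v
}

#' Read and write mooring series as CSV
#'
#' Plain-text interchange format: `#`-prefixed header lines carrying the
#' variable name, units and nominal depth, then an ISO-8601 `time` column and
#' `value`/`qc_flag` (and `actual_depth` when present). Values are written
#' with 17 significant digits so that a write/read round trip is bit-exact.
#'
#' @param x a [mooring_series()].
#' @param path file path.
#' @return `write_mooring_csv` returns `path` invisibly; `read_mooring_csv`
#'   returns a [mooring_series()].
#' @export
write_mooring_csv <- function(x, path) {
  stopifnot(inherits(x, "mooring_series"))
  num17 <- function(v) ifelse(is.na(v), "NA", sprintf("%.17g", v))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("#variable: %s", attr(x, "variable")),
    sprintf("#units: %s", attr(x, "units")),
    sprintf("#nominal_depth: %s", num17(attr(x, "nominal_depth")))
  ), con)
  df <- as.data.frame(x)
  df$time <- format(df$time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  df$value <- num17(df$value)
  if ("actual_depth" %in% names(df)) {
    df$actual_depth <- num17(df$actual_depth)
  }
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_mooring_csv
#' @export
read_mooring_csv <- function(path) {
  lines <- readLines(path, n = 10L)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    ln <- grep(paste0("^#", key, ": "), hdr, value = TRUE)
    if (!length(ln)) return(NA_character_)
    sub(paste0("^#", key, ": "), "", ln[1])
  }
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  df$value <- as.numeric(df$value)
  mooring_series(
    time = as.POSIXct(df$time, format = "%Y-%m-%dT%H:%M:%OSZ", tz = "UTC"),
    value = df$value,
    variable = get("variable"),
    units = get("units"),
    nominal_depth = as.numeric(get("nominal_depth")),
    actual_depth = if ("actual_depth" %in% names(df)) as.numeric(df$actual_depth),
    qc_flag = df$qc_flag
  )
}
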