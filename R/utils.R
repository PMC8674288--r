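# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

DAYS_PER_MONTH <- 30.44  # calendar-average month used for all duration reporting

MASKED_FLAGS <- c("blowdown", "missing")
QC_LEVELS <- c("ok", "below_detection", "blowdown", "missing")

is_masked <- function(qc) qc %in% MASKED_FLAGS

as_utc <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  if (inherits(x, "Date")) return(as.POSIXct(as.character(x), tz = "UTC"))
  as.POSIXct(x, tz = "UTC")
}

stopifnot_scalar <- function(x, name = deparse(substitute(x))) {
  if (length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
}

# days since an origin, as numeric (sub-day resolution preserved)
num_days <- function(time, origin = time[1]) {
  as.numeric(difftime(as_utc(time), as_utc(origin), units = "days"))
}
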