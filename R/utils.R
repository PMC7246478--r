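# Internal helpers: naive-clock datetimes and classed error conditions.

# All timestamps in the package are naive local clock times.  They are stored
# as POSIXct in UTC so that arithmetic is pure clock arithmetic with no
# daylight-saving jumps.
.nx_tz <- "UTC"

nx_stop <- function(class, msg, ...) {
  stop(errorCondition(msg, ..., class = c(class, "noisecross_error")))
}

#' Parse ISO-8601 local datetimes
#'
#' Accepts `"YYYY-MM-DDTHH:MM:SS"` (a space instead of `T` is tolerated) and
#' returns POSIXct clock times with no timezone semantics.
#' @param x character vector (POSIXct passed through).
#' @return POSIXct vector; elements that fail to parse are `NA`.
#' @keywords internal
#' @noRd
nx_parse_datetime <- function(x) {
  if (inherits(x, "POSIXct")) {
    return(as.POSIXct(as.numeric(x), origin = "1970-01-01", tz = .nx_tz))
  }
  x <- sub("T", " ", as.character(x), fixed = TRUE)
  as.POSIXct(x, tz = .nx_tz, format = "%Y-%m-%d %H:%M:%S")
}

# seconds since local midnight
nx_clock_secs <- function(dt) {
  lt <- as.POSIXlt(dt, tz = .nx_tz)
  lt$hour * 3600 + lt$min * 60 + lt$sec
}

# POSIXct at `secs` seconds after local midnight of `date`
nx_at <- function(date, secs) {
  as.POSIXct(paste(format(date), "00:00:00"), tz = .nx_tz) + secs
}

nx_year <- function(dt) as.POSIXlt(dt, tz = .nx_tz)$year + 1900L

nx_date <- function(dt) as.Date(format(dt, tz = .nx_tz))

# parse "HH:MM" clock string to seconds since midnight
nx_hm_secs <- function(hm) {
  p <- as.integer(strsplit(hm, ":", fixed = TRUE)[[1]])
  p[1] * 3600 + p[2] * 60
}

nx_fmt_dt <- function(dt) format(dt, "%Y-%m-%dT%H:%M:%S", tz = .nx_tz)

# 32-bit polynomial rolling hash of a character scalar; used for config
# fingerprints in run manifests (stable across platforms, no dependency).
nx_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483648
  sprintf("%08x", as.integer(h))
}

nx_msg <- function(quiet, ...) {
  if (!isTRUE(quiet)) message(...)
}
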