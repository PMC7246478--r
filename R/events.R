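# Case-crossover events: death classification, nighttime exposure windows
# and time-stratified control sampling.

# Nominal clock spans of the fixed nighttime windows (seconds).  The three
# sub-windows early_night, core_night and early_morning partition the
# overall night 23:00-07:00 exactly.
.window_T <- c(evening = 14400L, early_night = 1800L, core_night = 23400L,
               early_morning = 3600L, overall_night = 28800L, last2h = 7200L)

#' Classify a death as daytime or nighttime
#'
#' Deaths between 07:00 and 23:00 (half-open, `[07:00, 23:00)`) are daytime
#' deaths and receive the five fixed windows of the preceding night; deaths
#' between 23:00 and 07:00 are nighttime deaths and receive the 2-hour
#' window preceding the time of death.
#'
#' @param death_dt POSIXct vector of death datetimes (local clock).
#' @return Character vector, `"daytime"` or `"nighttime"`.
#' @export
#' @examples
#' classify_death(as.POSIXct("2010-03-10 14:30:00", tz = "UTC"))
classify_death <- function(death_dt) {
  s <- nx_clock_secs(death_dt)
  ifelse(s >= 7 * 3600 & s < 23 * 3600, "daytime", "nighttime")
}

#' Exposure windows for one event date
#'
#' For a daytime death, returns the five fixed windows of the night
#' preceding the event date: evening 19:00-23:00, early night 23:00-23:30
#' (reserved for delayed flights), core night 23:30-06:00 (flight ban),
#' early morning 06:00-07:00, and the overall night 23:00-07:00 — all
#' anchored so that the night block ends at 07:00 on `event_date`.  For a
#' nighttime death, returns the single 2-hour window ending at the death
#' clock time on the corresponding night of `event_date` (control nights
#' reuse the case's clock time).  All windows are half-open `[start, end)`.
#'
#' @param event_date The case or control calendar date (`Date`).
#' @param death_class `"daytime"` or `"nighttime"`.
#' @param death_time For nighttime deaths, the clock time of death in
#'   seconds since midnight (or a POSIXct whose clock time is used).
#' @return A data frame with columns `window_id`, `start_dt`, `end_dt`,
#'   `T_seconds`.
#' @export
windows_for <- function(event_date, death_class = c("daytime", "nighttime"),
                        death_time = NULL) {
  death_class <- match.arg(death_class)
  event_date <- as.Date(event_date)
  if (death_class == "daytime") {
    prev <- event_date - 1L
    ids <- c("evening", "early_night", "core_night", "early_morning",
             "overall_night")
    start <- c(nx_at(prev, 19 * 3600), nx_at(prev, 23 * 3600),
               nx_at(prev, 23.5 * 3600), nx_at(event_date, 6 * 3600),
               nx_at(prev, 23 * 3600))
    end <- c(nx_at(prev, 23 * 3600), nx_at(prev, 23.5 * 3600),
             nx_at(event_date, 6 * 3600), nx_at(event_date, 7 * 3600),
             nx_at(event_date, 7 * 3600))
  } else {
    if (is.null(death_time))
      nx_stop("noisecross_event_error",
              "death_time is required for nighttime deaths")
    secs <- if (inherits(death_time, "POSIXct")) nx_clock_secs(death_time)
            else as.numeric(death_time)
    if (secs >= 7 * 3600 && secs < 23 * 3600)
      nx_stop("noisecross_event_error",
              "nighttime death_time must fall in [23:00, 07:00)")
    ids <- "last2h"
    end <- nx_at(event_date, secs)
    start <- end - .window_T[["last2h"]]
  }
  data.frame(window_id = ids, start_dt = start, end_dt = end,
             T_seconds = as.integer(round(as.numeric(end - start, units = "secs"))),
             stringsAsFactors = FALSE)
}

#' Time-stratified control dates
#'
#' Returns every date in the same calendar month and year as `case_date`
#' that falls on the same day of the week, excluding the case date itself —
#' the bidirectional time-stratified referent scheme, which yields 3 or 4
#' control dates per case.
#'
#' @param case_date A `Date` (or parseable string).
#' @return Sorted `Date` vector of 3 or 4 control dates.
#' @export
#' @examples
#' sample_controls(as.Date("2010-03-10"))  # the other Wednesdays of March
sample_controls <- function(case_date) {
  case_date <- as.Date(case_date)
  stopifnot(length(case_date) == 1, !is.na(case_date))
  first <- as.Date(format(case_date, "%Y-%m-01"))
  last <- seq(first, by = "1 month", length.out = 2)[2] - 1L
  days <- seq(first, last, by = "1 day")
  ctrl <- days[format(days, "%u") == format(case_date, "%u") & days != case_date]
  sort(ctrl)
}

#' Build case and control exposure events for one death
#'
#' Combines [classify_death()], [sample_controls()] and [windows_for()]:
#' one case event per window on the death date, plus one control event per
#' window on every control date.  A daytime death with k controls yields
#' `5 * (1 + k)` events; a nighttime death yields `1 + k` events.
#'
#' @param death A one-row data frame or list with `person_id`, `death_dt`
#'   (POSIXct) and optionally `icd10`.
#' @return A data frame of exposure events with columns `person_id`,
#'   `event_kind` (`"case"`/`"control"`), `event_date`, `window_id`,
#'   `start_dt`, `end_dt`, `T_seconds`, `death_class`.
#' @export
build_events <- function(death) {
  dt <- nx_parse_datetime(death$death_dt)
  cls <- classify_death(dt)
  case_date <- nx_date(dt)
  dates <- c(case_date, sample_controls(case_date))
  kinds <- c("case", rep("control", length(dates) - 1L))
  out <- vector("list", length(dates))
  for (i in seq_along(dates)) {
    w <- windows_for(dates[i], cls, death_time = dt)
    out[[i]] <- data.frame(
      person_id = death$person_id, event_kind = kinds[i],
      event_date = dates[i], w, death_class = cls,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Build exposure events for a table of deaths
#'
#' @param deaths Data frame of death records (see [read_deaths()]).
#' @return Row-bound [build_events()] output for every death.
#' @export
build_events_all <- function(deaths) {
  if (nrow(deaths) == 0) {
    return(data.frame(person_id = character(), event_kind = character(),
                      event_date = as.Date(character()),
                      window_id = character(),
                      start_dt = as.POSIXct(character(), tz = .nx_tz),
                      end_dt = as.POSIXct(character(), tz = .nx_tz),
                      T_seconds = integer(), death_class = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, lapply(seq_len(nrow(deaths)), function(i)
    build_events(deaths[i, , drop = FALSE])))
  rownames(res) <- NULL
  res
}

#' Read death records
#'
#' Expects a CSV with columns `person_id,x,y,death_dt,icd10`: the geocoded
#' residence (projected metres), death datetime (ISO-8601 local clock) and
#' ICD-10 cause of death.  By default records are restricted to
#' cardiovascular causes (codes I00-I99).
#'
#' @param path Path to the deaths CSV.
#' @param icd_filter Keep only ICD-10 codes matching `I\\d\\d(\\.\\d+)?`.
#' @param quiet Suppress the filter-count message.
#' @return Data frame with `person_id`, `x`, `y`, `death_dt` (POSIXct),
#'   `icd10`.
#' @export
read_deaths <- function(path, icd_filter = TRUE, quiet = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("person_id", "x", "y", "death_dt", "icd10")
  miss <- setdiff(need, names(df))
  if (length(miss))
    nx_stop("noisecross_parse_error",
            sprintf("%s: missing columns: %s", path, paste(miss, collapse = ", ")))
  if (nrow(df) == 0) {
    return(data.frame(person_id = character(), x = numeric(), y = numeric(),
                      death_dt = as.POSIXct(character(), tz = .nx_tz),
                      icd10 = character(), stringsAsFactors = FALSE))
  }
  dt <- nx_parse_datetime(df$death_dt)
  if (anyNA(dt)) {
    row <- which(is.na(dt))[1]
    parse_fail(path, row + 1L,
               sprintf("malformed death datetime '%s'", df$death_dt[row]))
  }
  out <- data.frame(person_id = df$person_id,
                    x = as.numeric(df$x), y = as.numeric(df$y),
                    death_dt = dt, icd10 = df$icd10,
                    stringsAsFactors = FALSE)
  if (icd_filter) {
    keep <- grepl("^I\\d\\d(\\.\\d+)?$", out$icd10)
    nx_msg(quiet, sprintf("read_deaths: %d of %d records with cardiovascular ICD-10 cause retained",
                          sum(keep), nrow(out)))
    out <- out[keep, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Write exposure events to CSV
#'
#' Columns: `person_id,event_kind,event_date,window_id,start_dt,end_dt,death_class`.
#'
#' @param events Events data frame from [build_events_all()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  out <- data.frame(
    person_id = events$person_id, event_kind = events$event_kind,
    event_date = format(events$event_date), window_id = events$window_id,
    start_dt = nx_fmt_dt(events$start_dt), end_dt = nx_fmt_dt(events$end_dt),
    death_class = events$death_class, stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read exposure events from CSV
#'
#' Inverse of [write_events()]; recomputes `T_seconds` from the window
#' bounds.
#'
#' @param path Path to the events CSV.
#' @return Events data frame.
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (nrow(df) == 0) return(build_events_all(read_deaths_empty()))
  start <- nx_parse_datetime(df$start_dt)
  end <- nx_parse_datetime(df$end_dt)
  data.frame(person_id = df$person_id, event_kind = df$event_kind,
             event_date = as.Date(df$event_date), window_id = df$window_id,
             start_dt = start, end_dt = end,
             T_seconds = as.integer(round(as.numeric(end - start, units = "secs"))),
             death_class = df$death_class, stringsAsFactors = FALSE)
}

read_deaths_empty <- function() {
  data.frame(person_id = character(), x = numeric(), y = numeric(),
             death_dt = as.POSIXct(character(), tz = .nx_tz),
             icd10 = character(), stringsAsFactors = FALSE)
}
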