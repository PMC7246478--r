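# Airport movement lists: reading, type recovery, filtering and the
# audibility interval of each flight.

#' Read an airport movement list
#'
#' Expects a CSV with columns
#' `flight_id,timestamp,aircraft_type,tail_number,route,runway,procedure,mtow_kg`.
#' Timestamps are ISO-8601 local clock times (`YYYY-MM-DDTHH:MM:SS`), the
#' moment of touch-down (arrivals) or brake release (departures).  Procedure
#' codes are `D` (departure) and `A` (arrival).  Empty strings denote missing
#' aircraft type, tail number or route; such rows are retained, not dropped.
#'
#' @param path Path to the movements CSV.
#' @param group_map Optional named character vector mapping aircraft types to
#'   aircraft groups (many-to-one); types not named map to themselves.
#' @return A data frame of movements with columns as above plus
#'   `aircraft_group`; `timestamp` is POSIXct (naive local clock),
#'   `procedure` is `"departure"`/`"arrival"`.
#' @export
read_movements <- function(path, group_map = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("flight_id", "timestamp", "aircraft_type", "tail_number",
            "route", "runway", "procedure", "mtow_kg")
  miss <- setdiff(need, names(df))
  if (length(miss))
    nx_stop("noisecross_parse_error",
            sprintf("%s: missing columns: %s", path, paste(miss, collapse = ", ")))
  ts <- nx_parse_datetime(df$timestamp)
  if (anyNA(ts)) {
    row <- which(is.na(ts))[1]
    parse_fail(path, row + 1L,
               sprintf("malformed timestamp '%s'", df$timestamp[row]))
  }
  proc_ok <- df$procedure %in% c("D", "A")
  if (!all(proc_ok)) {
    row <- which(!proc_ok)[1]
    parse_fail(path, row + 1L,
               sprintf("unknown procedure code '%s'", df$procedure[row]))
  }
  mtow <- suppressWarnings(as.numeric(df$mtow_kg))
  if (any(is.na(mtow) | mtow <= 0)) {
    row <- which(is.na(mtow) | mtow <= 0)[1]
    parse_fail(path, row + 1L,
               sprintf("mtow_kg must be a positive number, got '%s'",
                       df$mtow_kg[row]))
  }
  blank_na <- function(x) ifelse(nzchar(trimws(x)), x, NA_character_)
  out <- data.frame(
    flight_id = df$flight_id,
    timestamp = ts,
    aircraft_type = blank_na(df$aircraft_type),
    tail_number = blank_na(df$tail_number),
    route = blank_na(df$route),
    runway = df$runway,
    procedure = ifelse(df$procedure == "D", "departure", "arrival"),
    mtow_kg = mtow,
    stringsAsFactors = FALSE
  )
  assign_groups(out, group_map)
}

#' Derive aircraft groups from aircraft types
#'
#' Footprints are computed per aircraft group (types with similar flight
#' performance).  The mapping is many-to-one; the default is the identity
#' (each type is its own group).
#'
#' @param movements Movements data frame (see [read_movements()]).
#' @param group_map Optional named character vector `type -> group`.
#' @return `movements` with an `aircraft_group` column (`NA` where the type
#'   is missing).
#' @export
assign_groups <- function(movements, group_map = NULL) {
  grp <- movements$aircraft_type
  if (!is.null(group_map)) {
    hit <- match(grp, names(group_map))
    grp[!is.na(hit)] <- unname(group_map[hit[!is.na(hit)]])
  }
  movements$aircraft_group <- grp
  movements
}

#' Recover missing aircraft types from a tail-number registry
#'
#' Flights with a missing aircraft type but a known tail number are matched
#' against a registry of tail-number registrations (`tail_number`,
#' `valid_from`, `valid_to`, `aircraft_type`); when the flight date falls in
#' a registration's validity interval the type is filled in.  Present types
#' are never overwritten; unmatched rows stay missing.
#'
#' @param movements Movements data frame.
#' @param registry Data frame with columns `tail_number`, `valid_from`,
#'   `valid_to` (dates or parseable strings, inclusive) and `aircraft_type`.
#'   Validity intervals must not overlap within a tail number.
#' @param group_map Passed to [assign_groups()] to refresh groups after
#'   recovery.
#' @param quiet Suppress the recovery-count message.
#' @return `movements` with recovered types; the number of recoveries is
#'   attached as attribute `n_recovered`.
#' @export
recover_types <- function(movements, registry, group_map = NULL, quiet = FALSE) {
  registry$valid_from <- as.Date(registry$valid_from)
  registry$valid_to <- as.Date(registry$valid_to)
  # registry sanity: per-tail validity intervals must not overlap
  for (tn in unique(registry$tail_number)) {
    iv <- registry[registry$tail_number == tn, , drop = FALSE]
    iv <- iv[order(iv$valid_from), , drop = FALSE]
    if (nrow(iv) > 1 && any(iv$valid_from[-1] <= iv$valid_to[-nrow(iv)]))
      nx_stop("noisecross_registry_error",
              sprintf("overlapping validity intervals for tail number '%s'", tn))
  }
  todo <- which(is.na(movements$aircraft_type) & !is.na(movements$tail_number))
  n_rec <- 0L
  if (length(todo)) {
    dates <- nx_date(movements$timestamp[todo])
    for (k in seq_along(todo)) {
      i <- todo[k]
      hit <- registry$tail_number == movements$tail_number[i] &
        registry$valid_from <= dates[k] & registry$valid_to >= dates[k]
      if (any(hit)) {
        movements$aircraft_type[i] <- registry$aircraft_type[which(hit)[1]]
        n_rec <- n_rec + 1L
      }
    }
  }
  nx_msg(quiet, sprintf("recovered aircraft type for %d of %d flights with missing type",
                        n_rec, sum(is.na(movements$aircraft_type)) + n_rec))
  movements <- assign_groups(movements, group_map)
  attr(movements, "n_recovered") <- n_rec
  movements
}

#' Filter a movement list to relevant flights
#'
#' Retains large aircraft (maximum take-off weight strictly above
#' `min_mtow_kg`; the default 8618 kg cut-off excludes small aircraft whose
#' nighttime traffic is negligible) and, by default, drops flights with a
#' missing air route (their footprint cannot be identified).
#'
#' @param movements Movements data frame.
#' @param min_mtow_kg Strict MTOW threshold in kg; a flight at exactly this
#'   weight is excluded.
#' @param drop_missing_route Drop flights whose route is missing.
#' @param quiet Suppress the exclusion-count message.
#' @return Filtered movements; exclusion counts by reason are attached as
#'   attribute `exclusions` (`n_light`, `n_missing_route`, `n_excluded`).
#' @export
filter_flights <- function(movements, min_mtow_kg = 8618,
                           drop_missing_route = TRUE, quiet = FALSE) {
  light <- movements$mtow_kg <= min_mtow_kg
  no_route <- is.na(movements$route)
  drop <- light | (drop_missing_route & no_route)
  out <- movements[!drop, , drop = FALSE]
  rownames(out) <- NULL
  excl <- c(n_light = sum(light),
            n_missing_route = if (drop_missing_route) sum(no_route) else 0L,
            n_excluded = sum(drop))
  nx_msg(quiet, sprintf(
    "filter_flights: retained %d of %d (excluded %d light [<=%g kg], %d missing route; %d total)",
    nrow(out), nrow(movements), excl["n_light"], min_mtow_kg,
    excl["n_missing_route"], excl["n_excluded"]))
  attr(out, "exclusions") <- excl
  out
}

#' Audibility interval of each flight
#'
#' The movement timestamp is the moment of touch-down (arrival) or brake
#' release (departure); the aircraft is audible to residents farther from
#' the airport during a 10-minute buffer before landing, respectively after
#' departure.  A flight is attributed to an exposure window when its
#' audibility interval overlaps the window.
#'
#' @param movements Movements data frame (one or more rows).
#' @param buffer_min Buffer length in minutes (default 10).
#' @return A data frame with POSIXct columns `start` and `end`
#'   (`end - start` equals the buffer), one row per movement.
#' @export
audible_interval <- function(movements, buffer_min = 10) {
  buf <- buffer_min * 60
  dep <- movements$procedure == "departure"
  start <- movements$timestamp - ifelse(dep, 0, buf)
  end <- movements$timestamp + ifelse(dep, buf, 0)
  data.frame(start = start, end = end)
}
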