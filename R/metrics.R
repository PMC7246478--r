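# Decibel arithmetic and the three per-event exposure metrics:
# L_Aeq, maximum L_Amax, and NAT (number above threshold).

#' Energetic sum of decibel levels
#'
#' Combines levels by summing their linear energies:
#' `10 * log10(sum(10^(L/10)))`.  The empty sum carries no energy and
#' returns `-Inf`, which downstream propagates to the zero-dB rule of
#' [laeq_from_lae()].
#'
#' @param levels Numeric vector of levels in dB (may be empty).
#' @return Scalar dB value (`-Inf` for an empty input).
#' @export
#' @examples
#' energetic_sum(c(70, 70))  # 73.0103
energetic_sum <- function(levels) {
  if (length(levels) == 0) return(-Inf)
  if (!all(is.finite(levels)))
    nx_stop("noisecross_metric_error", "levels must be finite")
  10 * log10(sum(10^(levels / 10)))
}

#' Equivalent continuous sound level from a total sound exposure level
#'
#' `L_Aeq = L_AE,total - 10 * log10(T / t0)` with the reference time
#' `t0 = 1 s`.  Windows with no flight (no energy, `-Inf` input) and windows
#' whose L_Aeq would be negative are set to 0 dB.
#'
#' @param lae_total Total (energetically summed) L_AE in dB, or `-Inf` for
#'   no energy.
#' @param T_seconds Window duration in seconds (must be positive).
#' @return L_Aeq in dB (never negative).
#' @export
#' @examples
#' laeq_from_lae(90, 28800)  # overall night window
laeq_from_lae <- function(lae_total, T_seconds) {
  if (!is.numeric(T_seconds) || length(T_seconds) != 1 || is.na(T_seconds) ||
      T_seconds <= 0)
    nx_stop("noisecross_metric_error", "T_seconds must be a positive number")
  if (!is.finite(lae_total)) return(0)
  max(0, lae_total - 10 * log10(T_seconds))
}

#' Maximum event level within a window
#'
#' The highest per-flight L_Amax observed within the window; 0 dB when no
#' flight was found (the no-flight zero rule, with `n_flights` recorded
#' separately so true silence remains distinguishable).
#'
#' @param lamax Numeric vector of per-flight L_Amax values in dB.
#' @return Scalar dB value.
#' @export
lamax_of_event <- function(lamax) {
  if (length(lamax) == 0) return(0)
  max(lamax)
}

#' Number of flights above a threshold
#'
#' Counts flights whose L_Amax exceeds `threshold` (strictly greater by
#' default; a flight at exactly the threshold is not counted).
#'
#' @param lamax Numeric vector of per-flight L_Amax values in dB.
#' @param threshold Threshold in dB (default 55, the NAT_55 metric).
#' @param strict Use strict `>` (default); set `FALSE` for `>=`.
#' @return Non-negative integer count.
#' @export
nat <- function(lamax, threshold = 55, strict = TRUE) {
  if (length(lamax) == 0) return(0L)
  if (strict) sum(lamax > threshold) else sum(lamax >= threshold)
}

# flights attributed to a half-open window [start, end)
flights_in_window <- function(movements, start, end,
                              membership = c("overlap", "point"),
                              buffer_min = 10) {
  membership <- match.arg(membership)
  if (membership == "overlap") {
    aud <- audible_interval(movements, buffer_min)
    which(as.numeric(aud$start) < as.numeric(end) &
            as.numeric(aud$end) > as.numeric(start))
  } else {
    ts <- as.numeric(movements$timestamp)
    which(ts >= as.numeric(start) & ts < as.numeric(end))
  }
}

#' Compute the exposure record for one event window
#'
#' Selects the flights whose audibility interval overlaps the event window
#' with positive measure (or, with `membership = "point"`, whose raw
#' timestamp falls inside it), resolves each flight's footprint (with
#' fallback), interpolates L_AE and L_Amax at the residential geocode, and
#' aggregates: L_Aeq via energetic summation and the window-duration
#' normalisation, the window maximum of L_Amax, and NAT.
#'
#' @param event A one-row data frame or list with `start_dt`, `end_dt` and
#'   `T_seconds` (see [windows_for()]).
#' @param movements Filtered movements data frame with `aircraft_group` set.
#' @param store A [footprint_store()].
#' @param geocode Numeric length-2 `(x, y)`, the residential geocode in
#'   projected metres.
#' @param membership Window-membership rule: `"overlap"` (audibility
#'   interval overlaps the window; default) or `"point"` (raw timestamp in
#'   window).
#' @param nat_threshold,nat_strict Passed to [nat()].
#' @param buffer_min Audibility buffer in minutes (default 10).
#' @param cache Optional environment used to memoise footprint lookups and
#'   interpolated levels across calls (same store and geocode set).
#' @param quiet Suppress footprint-fallback messages.
#' @return A list with `laeq` (dB), `lamax_max` (dB), `nat55` (integer),
#'   `n_flights` (integer) and `n_fallbacks` (integer).
#' @export
compute_exposure <- function(event, movements, store, geocode,
                             membership = c("overlap", "point"),
                             nat_threshold = 55, nat_strict = TRUE,
                             buffer_min = 10, cache = NULL, quiet = FALSE) {
  membership <- match.arg(membership)
  sel <- flights_in_window(movements, event$start_dt, event$end_dt,
                           membership, buffer_min)
  if (length(sel) == 0) {
    return(list(laeq = 0, lamax_max = 0, nat55 = 0L, n_flights = 0L,
                n_fallbacks = 0L))
  }
  fl <- movements[sel, , drop = FALSE]
  bad <- is.na(fl$aircraft_group) | is.na(fl$route)
  if (any(bad))
    nx_stop("noisecross_missing_footprint",
            sprintf("flight %s has no aircraft group or route; footprint cannot be resolved",
                    fl$flight_id[which(bad)[1]]),
            flight_id = fl$flight_id[which(bad)[1]])
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  years <- nx_year(fl$timestamp)
  lae <- numeric(nrow(fl)); lamax <- numeric(nrow(fl)); n_fb <- 0L
  for (i in seq_len(nrow(fl))) {
    kid <- paste(years[i], fl$aircraft_group[i], fl$route[i],
                 fl$procedure[i], sep = "|")
    ck <- paste(kid, geocode[1], geocode[2])
    hit <- cache[[ck]]
    if (is.null(hit)) {
      gk <- paste0("grid::", kid)
      grid <- cache[[gk]]
      if (is.null(grid)) {
        grid <- tryCatch(
          lookup_footprint(store,
                           footprint_key(years[i], fl$aircraft_group[i],
                                         fl$route[i], fl$procedure[i]),
                           quiet = quiet),
          noisecross_missing_footprint = function(e)
            nx_stop("noisecross_missing_footprint",
                    sprintf("flight %s: %s", fl$flight_id[i], conditionMessage(e)),
                    flight_id = fl$flight_id[i])
        )
        cache[[gk]] <- grid
      }
      hit <- c(idw_interpolate(grid, geocode, "lae"),
               idw_interpolate(grid, geocode, "lamax"),
               as.numeric(!is.null(attr(grid, "requested_key"))))
      cache[[ck]] <- hit
    }
    lae[i] <- hit[1]; lamax[i] <- hit[2]; n_fb <- n_fb + as.integer(hit[3])
  }
  list(
    laeq = laeq_from_lae(energetic_sum(lae), event$T_seconds),
    lamax_max = lamax_of_event(lamax),
    nat55 = as.integer(nat(lamax, nat_threshold, nat_strict)),
    n_flights = nrow(fl),
    n_fallbacks = n_fb
  )
}

#' Compute exposure records for a table of events
#'
#' Vectorised driver over [compute_exposure()]: joins each event's person to
#' their geocode, computes the three metrics per event, and returns one row
#' per event in the input order.
#'
#' @param events Events data frame (see [build_events_all()]).
#' @param deaths Deaths data frame supplying `person_id`, `x`, `y`.
#' @param movements Filtered movements data frame.
#' @param store A [footprint_store()].
#' @inheritParams compute_exposure
#' @param quiet Suppress progress and fallback messages.
#' @return Data frame with columns `person_id`, `event_kind`, `event_date`,
#'   `window_id`, `laeq_db`, `lamax_db`, `nat55`, `n_flights`.  Summary
#'   counts (flights used, fallbacks, zero-exposure events) are attached as
#'   attribute `summary`.
#' @export
compute_exposures <- function(events, deaths, movements, store,
                              membership = c("overlap", "point"),
                              nat_threshold = 55, nat_strict = TRUE,
                              buffer_min = 10, quiet = TRUE) {
  membership <- match.arg(membership)
  gi <- match(events$person_id, deaths$person_id)
  if (anyNA(gi))
    nx_stop("noisecross_event_error",
            sprintf("no geocode for person '%s'",
                    events$person_id[which(is.na(gi))[1]]))
  cache <- new.env(parent = emptyenv())
  n <- nrow(events)
  laeq <- numeric(n); lamax <- numeric(n)
  nat55 <- integer(n); nfl <- integer(n); nfb <- integer(n)
  for (i in seq_len(n)) {
    r <- compute_exposure(events[i, , drop = FALSE], movements, store,
                          c(deaths$x[gi[i]], deaths$y[gi[i]]),
                          membership, nat_threshold, nat_strict,
                          buffer_min, cache = cache, quiet = quiet)
    laeq[i] <- r$laeq; lamax[i] <- r$lamax_max
    nat55[i] <- r$nat55; nfl[i] <- r$n_flights; nfb[i] <- r$n_fallbacks
  }
  out <- data.frame(
    person_id = events$person_id, event_kind = events$event_kind,
    event_date = events$event_date, window_id = events$window_id,
    laeq_db = laeq, lamax_db = lamax, nat55 = nat55, n_flights = nfl,
    stringsAsFactors = FALSE
  )
  smry <- c(n_events = n, n_flight_links = sum(nfl),
            n_fallbacks = sum(nfb), n_zero_exposure = sum(nfl == 0L))
  nx_msg(quiet, sprintf(
    "compute_exposures: %d events, %d flight links, %d footprint fallbacks, %d zero-exposure events",
    smry["n_events"], smry["n_flight_links"], smry["n_fallbacks"],
    smry["n_zero_exposure"]))
  attr(out, "summary") <- smry
  out
}

#' Write exposure records to CSV
#'
#' Columns `person_id,event_kind,event_date,window_id,laeq_db,lamax_db,nat55,n_flights`;
#' levels are rounded to 3 decimal places on output (internal computation is
#' double precision throughout).
#'
#' @param exposure Data frame from [compute_exposures()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_exposure <- function(exposure, path) {
  out <- exposure
  out$event_date <- format(out$event_date)
  out$laeq_db <- sprintf("%.3f", out$laeq_db)
  out$lamax_db <- sprintf("%.3f", out$lamax_db)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
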