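# Seeded synthetic generators: footprint grids, nightly flight schedules
# with a flight ban, a tail-number registry, and geocoded death records.
# They emulate the structure the exposure-assessment method assumes so the
# full pipeline runs without restricted data.

#' Synthetic study configuration
#'
#' Bundles every parameter of the synthetic generators.  Defaults describe a
#' compact study: a 20 x 20 km projected region, three air routes crossing
#' it, two heavy aircraft groups plus one light type, a nightly flight
#' schedule with a 23:30-06:00 flight ban and occasional delayed flights in
#' 23:00-23:30, and death records scattered uniformly over the region.
#'
#' @param seed Master integer seed; the three generators draw from
#'   independent streams derived from it.
#' @param study_span Integer length-2, first and last calendar year.
#' @param region Named numeric `(xmin, ymin, xmax, ymax)` in projected
#'   metres.
#' @param routes Data frame with columns `name`, `x0`, `y0`, `x1`, `y1`
#'   (route axis segment) and `weight` (base traffic share).
#' @param aircraft Data frame with columns `type`, `group`, `mtow_kg`,
#'   `source_level` (on-axis L_AE in dB) and `prob` (fleet share).
#' @param nightly_flight_rate Mean number of flights per night (Poisson).
#' @param ban_start,ban_end Clock times `"HH:MM"` bounding the flight ban.
#' @param delayed_flight_prob Probability that a flight is displaced into
#'   the delayed-flight slot `[23:00, ban_start)`.
#' @param missing_type_prob Fraction of movement rows with a missing
#'   aircraft type.
#' @param recoverable_frac Of the missing-type rows, the fraction whose tail
#'   number appears in the generated registry (and is thus recoverable).
#' @param missing_route_prob Fraction of rows with a missing air route.
#' @param footprint_gap_prob Probability that a (year, group, route,
#'   procedure) footprint after the first year is omitted, exercising the
#'   nearest-year fallback.
#' @param n_deaths Number of death records.
#' @param daytime_frac Fraction of deaths occurring in `[07:00, 23:00)`.
#' @param cell_size Footprint receiver spacing in metres.
#' @param decay_k,decay_d0 Toy footprint decay: level =
#'   `source_level - decay_k * log10(1 + d / decay_d0)` with `d` the
#'   distance (m) to the route axis.
#' @param lamax_offset L_Amax is L_AE minus this offset (dB); a single
#'   aircraft event's energy exceeds its maximum level by roughly
#'   10 log10 of its effective duration.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         study_span = c(2010L, 2011L),
                         region = c(xmin = 680000, ymin = 240000,
                                    xmax = 700000, ymax = 260000),
                         routes = NULL,
                         aircraft = NULL,
                         nightly_flight_rate = 30,
                         ban_start = "23:30", ban_end = "06:00",
                         delayed_flight_prob = 0.05,
                         missing_type_prob = 0.04,
                         recoverable_frac = 0.75,
                         missing_route_prob = 0.01,
                         footprint_gap_prob = 0.1,
                         n_deaths = 200L,
                         daytime_frac = 2 / 3,
                         cell_size = 250,
                         decay_k = 22, decay_d0 = 300,
                         lamax_offset = 10) {
  if (is.null(routes)) {
    xm <- (region["xmin"] + region["xmax"]) / 2
    ym <- (region["ymin"] + region["ymax"]) / 2
    routes <- data.frame(
      name = c("R16", "R28", "R34"),
      x0 = c(region[["xmin"]], region[["xmin"]], xm),
      y0 = c(ym, region[["ymin"]], region[["ymin"]]),
      x1 = c(region[["xmax"]], region[["xmax"]], xm),
      y1 = c(ym, region[["ymax"]], region[["ymax"]]),
      weight = c(0.5, 0.3, 0.2),
      stringsAsFactors = FALSE
    )
  }
  if (is.null(aircraft)) {
    aircraft <- data.frame(
      type = c("A320", "B738", "A333", "C525"),
      group = c("NB", "NB", "WB", "LIGHT"),
      mtow_kg = c(78000, 79000, 230000, 4700),
      source_level = c(98, 98, 103, 88),
      prob = c(0.40, 0.30, 0.20, 0.10),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(nightly_flight_rate >= 0,
            delayed_flight_prob >= 0, delayed_flight_prob <= 1,
            missing_type_prob >= 0, missing_type_prob <= 1,
            missing_route_prob >= 0, missing_route_prob <= 1,
            footprint_gap_prob >= 0, footprint_gap_prob <= 1,
            daytime_frac >= 0, daytime_frac <= 1,
            region[["xmax"]] > region[["xmin"]],
            region[["ymax"]] > region[["ymin"]],
            n_deaths >= 1)
  structure(
    list(seed = as.integer(seed), study_span = as.integer(study_span),
         region = region, routes = routes, aircraft = aircraft,
         nightly_flight_rate = nightly_flight_rate,
         ban_start = ban_start, ban_end = ban_end,
         delayed_flight_prob = delayed_flight_prob,
         missing_type_prob = missing_type_prob,
         recoverable_frac = recoverable_frac,
         missing_route_prob = missing_route_prob,
         footprint_gap_prob = footprint_gap_prob,
         n_deaths = as.integer(n_deaths), daytime_frac = daytime_frac,
         cell_size = cell_size, decay_k = decay_k, decay_d0 = decay_d0,
         lamax_offset = lamax_offset),
    class = "synth_config"
  )
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf("<synth_config> seed %d, years %d-%d, %d routes, %d aircraft types, %d deaths\n",
              x$seed, x$study_span[1], x$study_span[2], nrow(x$routes),
              nrow(x$aircraft), x$n_deaths))
  invisible(x)
}

# independent substream seeds (kept below 2^31)
synth_seed <- function(cfg, stream) {
  (abs(cfg$seed) * 7919 + stream * 104729) %% 2147483647
}

# distance from points (x, y) to the segment (x0,y0)-(x1,y1)
seg_dist <- function(x, y, x0, y0, x1, y1) {
  vx <- x1 - x0; vy <- y1 - y0
  len2 <- vx^2 + vy^2
  t <- if (len2 == 0) 0 else pmin(1, pmax(0, ((x - x0) * vx + (y - y0) * vy) / len2))
  sqrt((x - (x0 + t * vx))^2 + (y - (y0 + t * vy))^2)
}

#' Generate synthetic footprint grids
#'
#' For every (year, heavy aircraft group, route, procedure) combination a
#' grid over the study region at `cfg$cell_size` spacing is produced with a
#' toy monotone decay away from the route axis:
#' `lae = source_level - decay_k * log10(1 + d / decay_d0)` (plus a small
#' deterministic per-grid year effect), `lamax = lae - lamax_offset`.  With
#' `footprint_gap_prob > 0` some year combinations after the first year are
#' omitted so the nearest-year fallback of [lookup_footprint()] is
#' exercised.  Deterministic for a given config.
#'
#' @param cfg A [synth_config()].
#' @return A [footprint_store()].
#' @export
make_footprints <- function(cfg) {
  set.seed(synth_seed(cfg, 1L))
  cs <- cfg$cell_size
  xs <- seq(cfg$region[["xmin"]], cfg$region[["xmax"]], by = cs)
  ys <- seq(cfg$region[["ymin"]], cfg$region[["ymax"]], by = cs)
  nx <- length(xs); ny <- length(ys)
  gx <- rep(xs, each = ny); gy <- rep(rev(ys), times = nx)  # row 1 = north
  heavy <- unique(cfg$aircraft[cfg$aircraft$mtow_kg > 8618,
                               c("group", "source_level")])
  years <- seq(cfg$study_span[1], cfg$study_span[2])
  grids <- list()
  for (g in seq_len(nrow(heavy))) {
    for (r in seq_len(nrow(cfg$routes))) {
      rt <- cfg$routes[r, ]
      d <- seg_dist(gx, gy, rt$x0, rt$y0, rt$x1, rt$y1)
      base <- heavy$source_level[g] - cfg$decay_k * log10(1 + d / cfg$decay_d0)
      for (proc in c("departure", "arrival")) {
        for (yi in seq_along(years)) {
          if (yi > 1 && stats::runif(1) < cfg$footprint_gap_prob) next
          jitter <- stats::runif(1, -1, 1)  # per-grid year effect, dB
          lae <- matrix(pmax(0, base + jitter), ny, nx)
          lamax <- matrix(pmax(0, base + jitter - cfg$lamax_offset), ny, nx)
          key <- footprint_key(years[yi], heavy$group[g], rt$name, proc)
          grids[[length(grids) + 1L]] <-
            footprint_grid(key, c(min(xs), min(ys)), lae, lamax, cs)
        }
      }
    }
  }
  footprint_store(grids)
}

# deterministic tail pool for one aircraft type
synth_tails <- function(type, n = 8L) sprintf("HB-%s%02d", type, seq_len(n))

#' Generate the synthetic tail-number registry
#'
#' One registration per tail in the pool, valid over the whole study span;
#' used by [recover_types()] to fill missing aircraft types.
#'
#' @param cfg A [synth_config()].
#' @return Data frame `tail_number, valid_from, valid_to, aircraft_type`.
#' @export
make_tail_registry <- function(cfg) {
  rows <- do.call(rbind, lapply(seq_len(nrow(cfg$aircraft)), function(i) {
    data.frame(tail_number = synth_tails(cfg$aircraft$type[i]),
               valid_from = sprintf("%d-01-01", cfg$study_span[1]),
               valid_to = sprintf("%d-12-31", cfg$study_span[2]),
               aircraft_type = cfg$aircraft$type[i],
               stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  rows
}

#' Generate a synthetic movement list
#'
#' Nightly flight counts are Poisson with mean `nightly_flight_rate`.  The
#' traffic share of each route is resampled every night (a weather proxy),
#' so the same geocode sees different exposure across nights.  Scheduled
#' flights fall in the evening (18:00-23:00) and early morning
#' (06:00-08:00); with probability `delayed_flight_prob` a flight is
#' displaced into the delayed-flight slot `[23:00, ban_start)`.  No flight
#' is generated inside the ban interval.  Configured fractions of rows have
#' a missing aircraft type (recoverable via the tail registry, except for a
#' share whose tail number is also unknown) or a missing route.
#' Deterministic for a given config.
#'
#' @param cfg A [synth_config()].
#' @return Movements data frame in the [read_movements()] layout (with
#'   `aircraft_group` assigned from the config's type-to-group map).
#' @export
make_movements <- function(cfg) {
  set.seed(synth_seed(cfg, 2L))
  dates <- seq(as.Date(sprintf("%d-01-01", cfg$study_span[1])),
               as.Date(sprintf("%d-12-31", cfg$study_span[2])), by = "1 day")
  ban_start <- nx_hm_secs(cfg$ban_start)
  ac <- cfg$aircraft
  n_nightly <- stats::rpois(length(dates), cfg$nightly_flight_rate)
  rows <- vector("list", length(dates))
  serial <- 0L
  for (di in seq_along(dates)) {
    n <- n_nightly[di]
    if (n == 0) next
    # per-night route regime (normalised Gamma weights around base shares)
    w <- stats::rgamma(nrow(cfg$routes), shape = 4 * cfg$routes$weight)
    w <- w / sum(w)
    route <- sample(cfg$routes$name, n, replace = TRUE, prob = w)
    ai <- sample(seq_len(nrow(ac)), n, replace = TRUE, prob = ac$prob)
    proc <- sample(c("departure", "arrival"), n, replace = TRUE)
    # scheduled slots: evening 18:00-23:00 (5 h) or morning 06:00-08:00 (2 h)
    evening <- stats::runif(n) < 5 / 7
    secs <- ifelse(evening,
                   18 * 3600 + stats::runif(n) * 5 * 3600,
                   6 * 3600 + stats::runif(n) * 2 * 3600)
    delayed <- stats::runif(n) < cfg$delayed_flight_prob
    secs[delayed] <- 23 * 3600 +
      stats::runif(sum(delayed)) * (ban_start - 23 * 3600)
    ts <- nx_at(dates[di], floor(secs))
    tail_no <- vapply(ai, function(a)
      sample(synth_tails(ac$type[a]), 1), character(1))
    type <- ac$type[ai]
    miss_t <- stats::runif(n) < cfg$missing_type_prob
    type[miss_t] <- NA_character_
    unrecoverable <- miss_t & stats::runif(n) >= cfg$recoverable_frac
    tail_no[unrecoverable] <- NA_character_
    route[stats::runif(n) < cfg$missing_route_prob] <- NA_character_
    rows[[di]] <- data.frame(
      flight_id = sprintf("F%07d", serial + seq_len(n)),
      timestamp = ts, aircraft_type = type, tail_number = tail_no,
      route = route,
      runway = ifelse(proc == "departure", "RWY28", "RWY34"),
      procedure = proc, mtow_kg = ac$mtow_kg[ai],
      stringsAsFactors = FALSE
    )
    serial <- serial + n
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  assign_groups(out, synth_group_map(cfg))
}

#' Type-to-group map implied by a synthetic configuration
#'
#' @param cfg A [synth_config()].
#' @return Named character vector `type -> group` for [assign_groups()].
#' @export
synth_group_map <- function(cfg) {
  stats::setNames(cfg$aircraft$group, cfg$aircraft$type)
}

#' Generate synthetic death records
#'
#' Geocodes uniform over the study region; death dates uniform over the
#' study span; the clock time is daytime (`[07:00, 23:00)`) with probability
#' `daytime_frac`, otherwise nighttime (`[23:00, 07:00)`), uniform within
#' the chosen period.  ICD-10 codes are sampled from I00-I99.
#' Deterministic for a given config.
#'
#' @param cfg A [synth_config()].
#' @return Deaths data frame in the [read_deaths()] layout.
#' @export
make_deaths <- function(cfg) {
  set.seed(synth_seed(cfg, 3L))
  n <- cfg$n_deaths
  dates <- seq(as.Date(sprintf("%d-01-01", cfg$study_span[1])),
               as.Date(sprintf("%d-12-31", cfg$study_span[2])), by = "1 day")
  day <- stats::runif(n) < cfg$daytime_frac
  secs <- ifelse(day,
                 7 * 3600 + stats::runif(n) * 16 * 3600,
                 (23 * 3600 + stats::runif(n) * 8 * 3600) %% 86400)
  data.frame(
    person_id = sprintf("P%05d", seq_len(n)),
    x = stats::runif(n, cfg$region[["xmin"]], cfg$region[["xmax"]]),
    y = stats::runif(n, cfg$region[["ymin"]], cfg$region[["ymax"]]),
    death_dt = nx_at(sample(dates, n, replace = TRUE), floor(secs)),
    icd10 = sprintf("I%02d", sample(0:99, n, replace = TRUE)),
    stringsAsFactors = FALSE
  )
}
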