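# Footprint grids: containers, inverse-distance interpolation and
# key-based lookup with fallback substitution.

#' Footprint key
#'
#' Identifies one noise footprint: the receiver grid of per-event levels for
#' flights of one aircraft group on one air route and procedure in one
#' calendar year, optionally split by time of day.
#'
#' @param year Integer calendar year.
#' @param aircraft_group Character label of the aircraft type group.
#' @param route Character label of the air route.
#' @param procedure `"departure"` or `"arrival"`.
#' @param time_of_day Optional, `"day"` or `"night"`; `NA` (default) for
#'   footprints not split by time of day.
#' @return An object of class `footprint_key`.
#' @export
#' @examples
#' footprint_key(2010, "NB", "R1", "departure")
footprint_key <- function(year, aircraft_group, route, procedure,
                          time_of_day = NA_character_) {
  procedure <- match.arg(procedure, c("departure", "arrival"))
  if (!is.na(time_of_day)) {
    time_of_day <- match.arg(time_of_day, c("day", "night"))
  }
  structure(
    list(year = as.integer(year),
         aircraft_group = as.character(aircraft_group),
         route = as.character(route),
         procedure = procedure,
         time_of_day = as.character(time_of_day)),
    class = "footprint_key"
  )
}

key_id <- function(key) {
  tod <- if (is.na(key$time_of_day)) NULL else key$time_of_day
  paste(c(key$year, key$aircraft_group, key$route, key$procedure, tod),
        collapse = "|")
}

#' @export
format.footprint_key <- function(x, ...) key_id(x)

#' @export
print.footprint_key <- function(x, ...) {
  cat("<footprint_key>", key_id(x), "\n")
  invisible(x)
}

#' Footprint grid
#'
#' A regular receiver grid of per-event noise levels for one [footprint_key()]:
#' the sound exposure level `lae` (L_AE, dB) and the maximum level `lamax`
#' (L_Amax, dB) a single flight of that group/route/procedure produces at each
#' receiver.  Receivers are spaced `cell_size` metres apart on a projected
#' metric grid; `origin` is the south-west receiver, and matrix row 1 is the
#' northernmost row (y decreases with row index).
#'
#' @param key A [footprint_key()].
#' @param origin Numeric length-2, `(x, y)` of the south-west receiver in
#'   projected metres.
#' @param lae,lamax Numeric matrices of identical dimension `(ny, nx)`,
#'   levels in dB; all values must be finite.
#' @param cell_size Receiver spacing in metres (default 250).
#' @return An object of class `footprint_grid`.
#' @export
footprint_grid <- function(key, origin, lae, lamax, cell_size = 250) {
  stopifnot(inherits(key, "footprint_key"))
  origin <- as.numeric(origin)
  if (length(origin) != 2 || !all(is.finite(origin)))
    nx_stop("noisecross_invalid_grid", "origin must be two finite coordinates")
  if (!is.numeric(cell_size) || length(cell_size) != 1 || cell_size <= 0)
    nx_stop("noisecross_invalid_grid", "cell_size must be a positive number")
  lae <- as.matrix(lae); lamax <- as.matrix(lamax)
  if (!identical(dim(lae), dim(lamax)))
    nx_stop("noisecross_invalid_grid", "lae and lamax must have identical shape")
  if (!all(is.finite(lae)) || !all(is.finite(lamax)))
    nx_stop("noisecross_invalid_grid", "all stored levels must be finite")
  structure(
    list(key = key, origin = origin, cell_size = as.numeric(cell_size),
         nx = ncol(lae), ny = nrow(lae), lae = lae, lamax = lamax),
    class = "footprint_grid"
  )
}

#' @export
print.footprint_grid <- function(x, ...) {
  cat(sprintf("<footprint_grid> %s\n  %d x %d receivers @ %g m, origin (%g, %g)\n",
              key_id(x$key), x$ny, x$nx, x$cell_size, x$origin[1], x$origin[2]))
  cat(sprintf("  L_AE   range [%.1f, %.1f] dB\n", min(x$lae), max(x$lae)))
  cat(sprintf("  L_Amax range [%.1f, %.1f] dB\n", min(x$lamax), max(x$lamax)))
  invisible(x)
}

# x/y coordinate of receiver at row-major index k (row 1 = north)
grid_coord <- function(grid, k) {
  r <- (k - 1L) %/% grid$nx + 1L
  c <- (k - 1L) %% grid$nx + 1L
  list(row = r, col = c,
       x = grid$origin[1] + (c - 1L) * grid$cell_size,
       y = grid$origin[2] + (grid$ny - r) * grid$cell_size)
}

grid_in_extent <- function(grid, x, y) {
  cs <- grid$cell_size
  x >= grid$origin[1] && x <= grid$origin[1] + (grid$nx - 1) * cs &&
    y >= grid$origin[2] && y <= grid$origin[2] + (grid$ny - 1) * cs
}

#' Four nearest receivers of a footprint grid
#'
#' Returns the four receiver points of `grid` closest to `point` in Euclidean
#' distance, with deterministic tie-breaking by row-major receiver index
#' (row 1 = northernmost row).
#'
#' @param grid A [footprint_grid()].
#' @param point Numeric length-2 `(x, y)` in projected metres.
#' @return A data frame with columns `index` (row-major receiver index,
#'   row 1 = north), `row`, `col` and `distance` (metres), sorted ascending
#'   by distance.
#' @export
nearest_four <- function(grid, point) {
  if (grid$nx * grid$ny < 4)
    nx_stop("noisecross_invalid_grid",
            "grid has fewer than 4 receiver points")
  point <- as.numeric(point)
  if (length(point) != 2 || !all(is.finite(point)))
    nx_stop("noisecross_invalid_grid", "point must be two finite coordinates")
  cs <- grid$cell_size
  # candidate receivers: a block around the enclosing cell; for any point in
  # or near the extent the four nearest receivers lie within +/-2 index steps
  # of the enclosing cell (clamped at the grid edges)
  u <- (point[1] - grid$origin[1]) / cs                       # 0-based col
  v <- (grid$origin[2] + (grid$ny - 1) * cs - point[2]) / cs  # 0-based row
  cols <- unique(pmin(pmax(floor(u) + (-2:3), 0), grid$nx - 1L))
  rows <- unique(pmin(pmax(floor(v) + (-2:3), 0), grid$ny - 1L))
  cand <- expand.grid(row = rows, col = cols)
  dx <- grid$origin[1] + cand$col * cs - point[1]
  dy <- grid$origin[2] + (grid$ny - 1 - cand$row) * cs - point[2]
  d <- sqrt(dx^2 + dy^2)
  idx <- as.integer(cand$row * grid$nx + cand$col + 1L)
  o <- order(d, idx)[1:4]
  data.frame(index = idx[o], row = as.integer(cand$row[o] + 1L),
             col = as.integer(cand$col[o] + 1L), distance = d[o])
}

#' Inverse-distance-weighted interpolation of a footprint grid
#'
#' Interpolates the stored level at an arbitrary receiver point from the four
#' nearest grid receivers using inverse distance weighting with exponent 1:
#' `L = (sum L_i / d_i) / (sum 1 / d_i)`.  If the point coincides with a
#' receiver (distance below `zero_tol`), that receiver's stored value is
#' returned exactly.  Interpolation operates on the dB values themselves, not
#' on energies.
#'
#' @param grid A [footprint_grid()].
#' @param point Numeric length-2 `(x, y)` in projected metres; must lie within
#'   the grid extent.
#' @param metric `"lae"` or `"lamax"`: which stored level to interpolate.
#' @param zero_tol Distances below this (metres) are treated as zero
#'   (geocode exactly on a receiver); default `1e-6`.
#' @return Interpolated level in dB (scalar).
#' @export
#' @examples
#' g <- footprint_grid(footprint_key(2010, "NB", "R1", "departure"),
#'                     origin = c(0, 0), cell_size = 250,
#'                     lae = matrix(60 + 1:9, 3, 3),
#'                     lamax = matrix(50 + 1:9, 3, 3))
#' idw_interpolate(g, c(125, 125), "lae")
idw_interpolate <- function(grid, point, metric = c("lae", "lamax"),
                            zero_tol = 1e-6) {
  metric <- match.arg(metric)
  point <- as.numeric(point)
  if (!grid_in_extent(grid, point[1], point[2]))
    nx_stop("noisecross_extent_error",
            sprintf("point (%g, %g) lies outside the extent of grid %s",
                    point[1], point[2], key_id(grid$key)))
  nf <- nearest_four(grid, point)
  vals <- grid[[metric]][cbind(nf$row, nf$col)]
  if (nf$distance[1] < zero_tol) return(vals[1])
  w <- 1 / nf$distance
  sum(vals * w) / sum(w)
}

#' Footprint store
#'
#' A searchable collection of [footprint_grid()] objects, indexed by key.
#'
#' @param grids A list of `footprint_grid` objects.
#' @return An object of class `footprint_store`.
#' @export
footprint_store <- function(grids = list()) {
  stopifnot(all(vapply(grids, inherits, logical(1), "footprint_grid")))
  ids <- vapply(grids, function(g) key_id(g$key), character(1))
  if (anyDuplicated(ids))
    nx_stop("noisecross_invalid_grid",
            paste("duplicate footprint keys:",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  names(grids) <- ids
  index <- data.frame(
    key_id = ids,
    year = vapply(grids, function(g) g$key$year, integer(1)),
    aircraft_group = vapply(grids, function(g) g$key$aircraft_group, character(1)),
    route = vapply(grids, function(g) g$key$route, character(1)),
    procedure = vapply(grids, function(g) g$key$procedure, character(1)),
    time_of_day = vapply(grids, function(g) g$key$time_of_day, character(1)),
    stringsAsFactors = FALSE
  )
  rownames(index) <- NULL
  structure(list(grids = grids, index = index), class = "footprint_store")
}

#' @export
print.footprint_store <- function(x, ...) {
  cat(sprintf("<footprint_store> %d footprints\n", length(x$grids)))
  if (nrow(x$index)) {
    cat(sprintf("  years %s; %d group(s), %d route(s)\n",
                paste(range(x$index$year), collapse = "-"),
                length(unique(x$index$aircraft_group)),
                length(unique(x$index$route))))
  }
  invisible(x)
}

#' @export
length.footprint_store <- function(x) length(x$grids)

#' Look up a footprint, with fallback substitution
#'
#' Resolves a [footprint_key()] against a [footprint_store()].  If the exact
#' key is absent, a similar footprint from a different year is substituted:
#' first the nearest other year for the same (aircraft group, route,
#' procedure, time of day), ties broken toward the earlier year; then the
#' nearest year for the same (aircraft group, route, procedure) ignoring time
#' of day.  Substitutions are reported via `message()` with both keys and
#' recorded in the returned grid's `"requested_key"` attribute.
#'
#' @param store A [footprint_store()].
#' @param key A [footprint_key()].
#' @param quiet Suppress the substitution message.
#' @return A `footprint_grid`.  When a fallback was used the attribute
#'   `requested_key` carries the originally requested key.
#' @export
lookup_footprint <- function(store, key, quiet = FALSE) {
  stopifnot(inherits(store, "footprint_store"), inherits(key, "footprint_key"))
  if (length(store$grids) == 0)
    nx_stop("noisecross_missing_footprint", "footprint store is empty",
            key = key_id(key))
  id <- key_id(key)
  g <- store$grids[[id]]
  if (!is.null(g)) return(g)
  idx <- store$index
  base <- idx$aircraft_group == key$aircraft_group &
    idx$route == key$route & idx$procedure == key$procedure
  # pass 1: same time-of-day stratum, nearest other year (earlier on ties)
  same_tod <- base & (is.na(idx$time_of_day) == is.na(key$time_of_day)) &
    (is.na(idx$time_of_day) | idx$time_of_day == key$time_of_day)
  cand <- idx[same_tod, , drop = FALSE]
  if (nrow(cand) == 0) cand <- idx[base, , drop = FALSE]  # pass 2: ignore tod
  if (nrow(cand) == 0)
    nx_stop("noisecross_missing_footprint",
            sprintf("no footprint for aircraft group '%s', route '%s', %s in any year (requested %s)",
                    key$aircraft_group, key$route, key$procedure, id),
            key = id)
  o <- order(abs(cand$year - key$year), cand$year)
  used <- cand$key_id[o[1]]
  nx_msg(quiet, sprintf("footprint fallback: %s -> %s", id, used))
  g <- store$grids[[used]]
  attr(g, "requested_key") <- id
  g
}
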