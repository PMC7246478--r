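# Shared fixture builders: everything is generated in code at test time.

# a grid whose receiver values are given row-wise (row 1 = north)
tiny_grid <- function(lae, lamax = lae - 10, origin = c(0, 0),
                      cell_size = 250, year = 2010, group = "NB",
                      route = "R1", procedure = "departure") {
  footprint_grid(footprint_key(year, group, route, procedure),
                 origin, lae, lamax, cell_size)
}

# random grid with seeded values
random_grid <- function(seed, nx = 6, ny = 5, origin = c(1000, 2000),
                        cell_size = 250, ...) {
  set.seed(seed)
  tiny_grid(matrix(runif(nx * ny, 40, 90), ny, nx),
            matrix(runif(nx * ny, 30, 80), ny, nx),
            origin = origin, cell_size = cell_size, ...)
}

# movements data frame from vectors; defaults make heavy departures whose
# group matches the tiny_grid() default key
make_mov <- function(timestamp, procedure = "departure",
                     aircraft_type = "NB", aircraft_group = aircraft_type,
                     tail_number = NA_character_, route = "R1",
                     runway = "RWY28", mtow_kg = 78000,
                     flight_id = NULL) {
  ts <- as.POSIXct(timestamp, tz = "UTC")
  n <- length(ts)
  if (is.null(flight_id)) flight_id <- sprintf("F%03d", seq_len(n))
  data.frame(flight_id = flight_id, timestamp = ts,
             aircraft_type = rep_len(aircraft_type, n),
             tail_number = rep_len(tail_number, n),
             route = rep_len(route, n), runway = rep_len(runway, n),
             procedure = rep_len(procedure, n),
             mtow_kg = rep_len(mtow_kg, n),
             aircraft_group = rep_len(aircraft_group, n),
             stringsAsFactors = FALSE)
}

# independent brute-force IDW oracle: flat loops, exhaustive distance sort,
# no shared code with the package internals
bf_idw <- function(grid, point, metric) {
  vals <- grid[[metric]]
  d <- numeric(grid$nx * grid$ny)
  v <- numeric(grid$nx * grid$ny)
  k <- 0
  for (r in seq_len(grid$ny)) {
    for (c in seq_len(grid$nx)) {
      k <- k + 1
      x <- grid$origin[1] + (c - 1) * grid$cell_size
      y <- grid$origin[2] + (grid$ny - r) * grid$cell_size
      d[k] <- sqrt((x - point[1])^2 + (y - point[2])^2)
      v[k] <- vals[r, c]
    }
  }
  o <- order(d, seq_along(d))[1:4]
  if (d[o[1]] < 1e-6) return(v[o[1]])
  num <- 0; den <- 0
  for (i in o) { num <- num + v[i] / d[i]; den <- den + 1 / d[i] }
  num / den
}

utc <- function(x) as.POSIXct(x, tz = "UTC")
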