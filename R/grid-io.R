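# Plain-text persistence of footprint grids.
#
# Grid dialect: header lines
#   key=<year>|<group>|<route>|<procedure>[|<tod>]
#   origin=<x> <y>
#   cell_size=<m>
#   nx=<int>
#   ny=<int>
# then a `#LAE` block and a `#LAMAX` block, each ny rows of nx
# whitespace-separated dB values, row 1 = northernmost row.

parse_fail <- function(path, line, msg) {
  nx_stop("noisecross_parse_error",
          sprintf("%s:%d: %s", path, line, msg), path = path, line = line)
}

#' Write a footprint grid to a plain-text file
#'
#' @param grid A [footprint_grid()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_grid()]
#' @export
write_grid <- function(grid, path) {
  stopifnot(inherits(grid, "footprint_grid"))
  fmt_row <- function(v) paste(formatC(v, digits = 12, format = "g"),
                               collapse = " ")
  lines <- c(
    paste0("key=", key_id(grid$key)),
    sprintf("origin=%s %s",
            formatC(grid$origin[1], digits = 12, format = "g"),
            formatC(grid$origin[2], digits = 12, format = "g")),
    sprintf("cell_size=%s", formatC(grid$cell_size, digits = 12, format = "g")),
    sprintf("nx=%d", grid$nx),
    sprintf("ny=%d", grid$ny),
    "#LAE",
    apply(grid$lae, 1, fmt_row),
    "#LAMAX",
    apply(grid$lamax, 1, fmt_row)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a footprint grid from a plain-text file
#'
#' Parses the grid dialect written by [write_grid()].  `write_grid()` followed
#' by `read_grid()` reproduces every field (levels to better than 1e-9 dB).
#' Malformed headers, non-rectangular level blocks and non-numeric cells
#' raise a parse error naming the offending line.
#'
#' @param path Path to a grid file.
#' @return A [footprint_grid()].
#' @export
read_grid <- function(path) {
  if (!file.exists(path))
    nx_stop("noisecross_parse_error", paste("no such file:", path))
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) && !startsWith(lines[i], "#")) {
    ln <- trimws(lines[i])
    if (nzchar(ln)) {
      eq <- regexpr("=", ln, fixed = TRUE)
      if (eq < 0) parse_fail(path, i, "expected 'name=value' header line")
      hdr[[substr(ln, 1, eq - 1)]] <- substr(ln, eq + 1, nchar(ln))
    }
    i <- i + 1L
  }
  for (need in c("key", "origin", "cell_size", "nx", "ny")) {
    if (is.null(hdr[[need]]))
      parse_fail(path, i, sprintf("missing '%s' header", need))
  }
  kp <- strsplit(hdr$key, "|", fixed = TRUE)[[1]]
  if (!length(kp) %in% c(4L, 5L))
    parse_fail(path, 1, "key must have 4 or 5 '|'-separated fields")
  key <- footprint_key(as.integer(kp[1]), kp[2], kp[3], kp[4],
                       if (length(kp) == 5) kp[5] else NA_character_)
  origin <- suppressWarnings(as.numeric(strsplit(trimws(hdr$origin), "\\s+")[[1]]))
  if (length(origin) != 2 || anyNA(origin))
    parse_fail(path, 1, "origin must be two numbers")
  cell_size <- suppressWarnings(as.numeric(hdr$cell_size))
  nx <- suppressWarnings(as.integer(hdr$nx))
  ny <- suppressWarnings(as.integer(hdr$ny))
  if (is.na(cell_size) || cell_size <= 0)
    parse_fail(path, 1, "cell_size must be a positive number")
  if (is.na(nx) || is.na(ny) || nx < 1 || ny < 1)
    parse_fail(path, 1, "nx and ny must be positive integers")

  read_block <- function(tag, at) {
    if (at > length(lines) || trimws(lines[at]) != tag)
      parse_fail(path, at, sprintf("expected '%s' block marker", tag))
    rows <- matrix(NA_real_, ny, nx)
    for (r in seq_len(ny)) {
      ln_no <- at + r
      if (ln_no > length(lines))
        parse_fail(path, ln_no, sprintf("unexpected end of file in %s block", tag))
      vals <- suppressWarnings(
        as.numeric(strsplit(trimws(lines[ln_no]), "\\s+")[[1]]))
      if (length(vals) != nx)
        parse_fail(path, ln_no,
                   sprintf("row %d of %s has %d values, expected %d",
                           r, tag, length(vals), nx))
      if (anyNA(vals))
        parse_fail(path, ln_no, sprintf("non-numeric cell in %s row %d", tag, r))
      rows[r, ] <- vals
    }
    list(m = rows, next_at = at + ny + 1L)
  }
  lae <- read_block("#LAE", i)
  lamax <- read_block("#LAMAX", lae$next_at)
  footprint_grid(key, origin, lae$m, lamax$m, cell_size)
}

#' Read a footprint grid from long-format CSV
#'
#' Alternative reader for a complete regular lattice given as columns
#' `x,y,lae,lamax` (one row per receiver).  Origin and cell size are inferred
#' from the coordinates; an incomplete or irregular lattice is an error.
#'
#' @param path Path to the CSV file.
#' @param key The [footprint_key()] to attach (the CSV carries no key).
#' @return A [footprint_grid()].
#' @export
read_grid_csv <- function(path, key) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x", "y", "lae", "lamax")
  if (!all(need %in% names(df)))
    nx_stop("noisecross_parse_error",
            sprintf("%s: expected columns %s", path, paste(need, collapse = ",")))
  xs <- sort(unique(df$x)); ys <- sort(unique(df$y))
  step <- function(v) {
    d <- diff(v)
    if (length(d) == 0) return(NA_real_)
    if (max(d) - min(d) > 1e-6 * max(d))
      nx_stop("noisecross_parse_error",
              sprintf("%s: irregular lattice spacing", path))
    d[1]
  }
  sx <- step(xs); sy <- step(ys)
  cs <- if (is.na(sx)) sy else sx
  if (is.na(cs))
    nx_stop("noisecross_parse_error", sprintf("%s: degenerate lattice", path))
  if (!is.na(sx) && !is.na(sy) && abs(sx - sy) > 1e-6 * cs)
    nx_stop("noisecross_parse_error",
            sprintf("%s: anisotropic lattice spacing", path))
  nx <- length(xs); ny <- length(ys)
  if (nrow(df) != nx * ny)
    nx_stop("noisecross_parse_error",
            sprintf("%s: %d rows but %d x %d lattice implies %d",
                    path, nrow(df), nx, ny, nx * ny))
  ci <- match(df$x, xs); ri <- ny + 1L - match(df$y, ys)  # row 1 = north
  if (anyDuplicated(cbind(ri, ci)))
    nx_stop("noisecross_parse_error", sprintf("%s: duplicate lattice points", path))
  lae <- matrix(NA_real_, ny, nx); lamax <- matrix(NA_real_, ny, nx)
  lae[cbind(ri, ci)] <- df$lae
  lamax[cbind(ri, ci)] <- df$lamax
  footprint_grid(key, c(min(xs), min(ys)), lae, lamax, cs)
}

#' Read a directory of footprint grid files into a store
#'
#' @param dir Directory containing `*.grid` files in the [write_grid()]
#'   dialect.
#' @param pattern Filename regexp (default `"\\.grid$"`).
#' @return A [footprint_store()].
#' @export
read_footprint_dir <- function(dir, pattern = "\\.grid$") {
  files <- sort(list.files(dir, pattern = pattern, full.names = TRUE))
  footprint_store(lapply(files, read_grid))
}

#' Write every grid of a store into a directory
#'
#' Files are named from the key, e.g. `2010_NB_R1_departure.grid`.
#'
#' @param store A [footprint_store()].
#' @param dir Output directory (created if needed).
#' @return The written file paths, invisibly.
#' @export
write_footprint_dir <- function(store, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(store$grids, function(g) {
    fn <- paste0(gsub("|", "_", key_id(g$key), fixed = TRUE), ".grid")
    write_grid(g, file.path(dir, fn))
    fn
  }, character(1))
  invisible(file.path(dir, paths))
}
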