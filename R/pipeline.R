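# Pipeline orchestration: simulate -> sample -> compute, file in / file out.

#' Write a full synthetic study to disk
#'
#' Generates footprint grids, a movement list, a tail registry and death
#' records from `cfg` and writes them under `dir`:
#' `footprints/*.grid`, `movements.csv`, `tail_registry.csv`, `deaths.csv`
#' and a `manifest.json` recording the seed and a config fingerprint.
#' Byte-stable for a given config.
#'
#' @param cfg A [synth_config()].
#' @param dir Output directory (created if needed).
#' @param quiet Suppress progress messages.
#' @return Named list of the written paths, invisibly.
#' @export
simulate_study <- function(cfg, dir, quiet = FALSE) {
  stopifnot(inherits(cfg, "synth_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  store <- make_footprints(cfg)
  mov <- make_movements(cfg)
  reg <- make_tail_registry(cfg)
  deaths <- make_deaths(cfg)
  fp_dir <- file.path(dir, "footprints")
  write_footprint_dir(store, fp_dir)
  paths <- list(
    footprints = fp_dir,
    movements = file.path(dir, "movements.csv"),
    tail_registry = file.path(dir, "tail_registry.csv"),
    deaths = file.path(dir, "deaths.csv"),
    group_map = file.path(dir, "group_map.csv"),
    manifest = file.path(dir, "manifest.json")
  )
  write_movements(mov, paths$movements)
  utils::write.csv(reg, paths$tail_registry, row.names = FALSE, quote = FALSE)
  write_deaths(deaths, paths$deaths)
  utils::write.csv(
    data.frame(aircraft_type = cfg$aircraft$type,
               aircraft_group = cfg$aircraft$group),
    paths$group_map, row.names = FALSE, quote = FALSE)
  manifest <- list(
    seed = cfg$seed,
    config_hash = nx_hash(paste(deparse(unclass(cfg)), collapse = "\n")),
    n_footprints = length(store),
    n_movements = nrow(mov),
    n_deaths = nrow(deaths),
    study_span = cfg$study_span
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  nx_msg(quiet, sprintf(
    "simulate_study: %d footprints, %d movements, %d deaths -> %s",
    length(store), nrow(mov), nrow(deaths), dir))
  invisible(paths)
}

#' Write a movement list to CSV
#'
#' Inverse of [read_movements()] (the derived `aircraft_group` column is not
#' written; it is re-derived on read).
#'
#' @param movements Movements data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_movements <- function(movements, path) {
  na_blank <- function(x) ifelse(is.na(x), "", x)
  out <- data.frame(
    flight_id = movements$flight_id,
    timestamp = nx_fmt_dt(movements$timestamp),
    aircraft_type = na_blank(movements$aircraft_type),
    tail_number = na_blank(movements$tail_number),
    route = na_blank(movements$route),
    runway = movements$runway,
    procedure = ifelse(movements$procedure == "departure", "D", "A"),
    mtow_kg = movements$mtow_kg,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write death records to CSV
#'
#' @param deaths Deaths data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_deaths <- function(deaths, path) {
  out <- data.frame(
    person_id = deaths$person_id,
    x = deaths$x, y = deaths$y,
    death_dt = nx_fmt_dt(deaths$death_dt),
    icd10 = deaths$icd10, stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the event-sampling stage on files
#'
#' Reads a deaths CSV, builds case and time-stratified control events for
#' every death, and writes the events CSV.
#'
#' @param deaths_csv Input deaths CSV path.
#' @param out_csv Output events CSV path.
#' @param icd_filter Passed to [read_deaths()].
#' @param quiet Suppress messages.
#' @return The events data frame, invisibly.
#' @export
run_sample <- function(deaths_csv, out_csv, icd_filter = TRUE, quiet = FALSE) {
  deaths <- read_deaths(deaths_csv, icd_filter = icd_filter, quiet = quiet)
  events <- build_events_all(deaths)
  write_events(events, out_csv)
  nx_msg(quiet, sprintf("run_sample: %d deaths -> %d events -> %s",
                        nrow(deaths), nrow(events), out_csv))
  invisible(events)
}

#' Run the exposure-computation stage on files
#'
#' Reads events, movements, deaths (for geocodes) and a footprint directory;
#' recovers missing aircraft types from the tail registry when given; applies
#' the large-aircraft and known-route filter; drops flights whose type is
#' still missing after recovery (their footprint can never be resolved; the
#' count is reported); computes the three exposure metrics per event; and
#' writes the exposure CSV.
#'
#' @param events_csv,movements_csv,deaths_csv Input CSV paths.
#' @param footprints_dir Directory of `*.grid` footprint files.
#' @param out_csv Output exposure CSV path.
#' @param tail_registry_csv Optional tail registry CSV for type recovery.
#' @param group_map Optional type-to-group map (see [assign_groups()]).
#' @param min_mtow_kg,membership,nat_threshold,nat_strict,buffer_min
#'   Pipeline parameters; see [filter_flights()] and [compute_exposure()].
#' @param quiet Suppress messages.
#' @return The exposure data frame, invisibly.
#' @export
run_compute <- function(events_csv, movements_csv, footprints_dir, deaths_csv,
                        out_csv, tail_registry_csv = NULL, group_map = NULL,
                        min_mtow_kg = 8618,
                        membership = c("overlap", "point"),
                        nat_threshold = 55, nat_strict = TRUE,
                        buffer_min = 10, quiet = FALSE) {
  membership <- match.arg(membership)
  events <- read_events(events_csv)
  deaths <- read_deaths(deaths_csv, icd_filter = FALSE, quiet = TRUE)
  mov <- read_movements(movements_csv, group_map = group_map)
  if (!is.null(tail_registry_csv)) {
    reg <- utils::read.csv(tail_registry_csv, stringsAsFactors = FALSE)
    mov <- recover_types(mov, reg, group_map = group_map, quiet = quiet)
  }
  mov <- filter_flights(mov, min_mtow_kg = min_mtow_kg, quiet = quiet)
  still_missing <- is.na(mov$aircraft_group)
  if (any(still_missing)) {
    nx_msg(quiet, sprintf(
      "run_compute: dropping %d flights with unrecoverable aircraft type",
      sum(still_missing)))
    mov <- mov[!still_missing, , drop = FALSE]
  }
  store <- read_footprint_dir(footprints_dir)
  exposure <- compute_exposures(events, deaths, mov, store,
                                membership = membership,
                                nat_threshold = nat_threshold,
                                nat_strict = nat_strict,
                                buffer_min = buffer_min, quiet = quiet)
  write_exposure(exposure, out_csv)
  nx_msg(quiet, sprintf("run_compute: %d exposure records -> %s",
                        nrow(exposure), out_csv))
  invisible(exposure)
}

#' Read a type-to-group map from CSV
#'
#' Expects columns `aircraft_type,aircraft_group`; the result feeds
#' [assign_groups()].  [simulate_study()] writes this file as
#' `group_map.csv`.
#'
#' @param path Path to the CSV.
#' @return Named character vector `type -> group`.
#' @export
read_group_map <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("aircraft_type", "aircraft_group") %in% names(df)))
    nx_stop("noisecross_parse_error",
            sprintf("%s: expected columns aircraft_type,aircraft_group", path))
  stats::setNames(df$aircraft_group, df$aircraft_type)
}

#' Run the simulation stage with a fresh config
#'
#' Thin wrapper over [synth_config()] + [simulate_study()] used by the
#' command-line interface.
#'
#' @param dir Output directory.
#' @param seed Master seed.
#' @param ... Further arguments to [synth_config()].
#' @param quiet Suppress messages.
#' @return Written paths, invisibly (see [simulate_study()]).
#' @export
run_simulate <- function(dir, seed = 1L, ..., quiet = FALSE) {
  simulate_study(synth_config(seed = seed, ...), dir, quiet = quiet)
}
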