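# Movement lists: parsing, type recovery, filtering and audibility.

mov_csv <- function(rows, path) {
  writeLines(c("flight_id,timestamp,aircraft_type,tail_number,route,runway,procedure,mtow_kg",
               rows), path)
  path
}

test_that("a well-formed movements CSV parses, keeping missing fields as NA", {
  path <- withr::local_tempfile(fileext = ".csv")
  mov_csv(c("F1,2010-03-09T19:30:00,A320,HB-AAA,R1,RWY28,D,78000",
            "F2,2010-03-09T22:10:00,,HB-BBB,R2,RWY34,A,79000",
            "F3,2010-03-10T06:15:00,A333,,,RWY28,D,230000"), path)
  m <- read_movements(path)
  expect_identical(nrow(m), 3L)
  expect_identical(m$procedure, c("departure", "arrival", "departure"))
  expect_true(is.na(m$aircraft_type[2]))  # retained, not dropped
  expect_true(is.na(m$route[3]) && is.na(m$tail_number[3]))
  expect_s3_class(m$timestamp, "POSIXct")
  # identity group derivation by default; map applies many-to-one
  expect_identical(m$aircraft_group, m$aircraft_type)
  m2 <- read_movements(path, group_map = c(A320 = "NB", A333 = "WB"))
  expect_identical(m2$aircraft_group, c("NB", NA, "WB"))
})

test_that("malformed rows raise parse errors with the row number", {
  path <- withr::local_tempfile(fileext = ".csv")
  mov_csv(c("F1,2010-03-09T19:30:00,A320,HB-AAA,R1,RWY28,D,78000",
            "F2,2010-13-45T99:00:00,A320,HB-AAA,R1,RWY28,D,78000"), path)
  err <- tryCatch(read_movements(path), error = function(e) e)
  expect_s3_class(err, "noisecross_parse_error")
  expect_match(conditionMessage(err), ":3:")  # header + 2 data rows

  mov_csv(c("F1,2010-03-09T19:30:00,A320,HB-AAA,R1,RWY28,X,78000"), path)
  expect_error(read_movements(path), regexp = "procedure",
               class = "noisecross_parse_error")
})

test_that("tail-registry recovery fills missing types and only those", {
  reg <- data.frame(
    tail_number = c("HB-AAA", "HB-AAA", "HB-CCC"),
    valid_from = c("2005-01-01", "2010-01-01", "2000-01-01"),
    valid_to = c("2009-12-31", "2015-12-31", "2015-12-31"),
    aircraft_type = c("A319", "A320", "B738"),
    stringsAsFactors = FALSE
  )
  m <- make_mov(c("2008-06-01 20:00:00", "2012-06-01 20:00:00",
                  "2012-06-01 21:00:00", "2012-06-01 22:00:00"),
                aircraft_type = c(NA, NA, NA, "A333"),
                tail_number = c("HB-AAA", "HB-AAA", "HB-ZZZ", "HB-CCC"))
  out <- recover_types(m, reg, quiet = TRUE)
  expect_identical(out$aircraft_type, c("A319", "A320", NA, "A333"))
  expect_identical(attr(out, "n_recovered"), 2L)

  # 10 movements, 4 missing, 3 recoverable -> 1 left missing
  m10 <- make_mov(rep("2012-06-01 20:00:00", 10),
                  aircraft_type = c(rep("A320", 6), rep(NA, 4)),
                  tail_number = c(rep(NA, 6), "HB-AAA", "HB-AAA", "HB-CCC", "HB-ZZZ"))
  out10 <- recover_types(m10, reg, quiet = TRUE)
  expect_identical(sum(is.na(out10$aircraft_type)), 1L)
  expect_identical(attr(out10, "n_recovered"), 3L)
})

test_that("recovery rejects overlapping registry intervals", {
  reg <- data.frame(tail_number = "HB-AAA",
                    valid_from = c("2005-01-01", "2008-01-01"),
                    valid_to = c("2008-06-30", "2015-12-31"),
                    aircraft_type = c("A319", "A320"))
  m <- make_mov("2010-01-01 20:00:00", aircraft_type = NA_character_,
                tail_number = "HB-AAA")
  expect_error(recover_types(m, reg, quiet = TRUE),
               class = "noisecross_registry_error")
})

test_that("the flight filter applies the strict weight cut-off and route rule", {
  # 20 flights: 5 light (one at exactly the cut-off), 2 missing-route,
  # 1 of them both -> 6 distinct exclusions, 14 retained
  m <- make_mov(rep("2010-03-09 20:00:00", 20),
                mtow_kg = c(rep(78000, 15), 8618, 8000, 5000, 4700, 3000),
                route = c(NA, rep("R1", 17), NA, "R1"))
  out <- filter_flights(m, quiet = TRUE)
  expect_identical(nrow(out), 14L)
  excl <- attr(out, "exclusions")
  expect_identical(unname(excl["n_light"]), 5L)
  expect_identical(unname(excl["n_missing_route"]), 2L)
  expect_identical(unname(excl["n_excluded"]), 6L)
  # exactly 8618 kg is excluded; 8619 kg is retained
  m2 <- make_mov(rep("2010-03-09 20:00:00", 2), mtow_kg = c(8618, 8619))
  expect_identical(filter_flights(m2, quiet = TRUE)$mtow_kg, 8619)
})

test_that("filtering is idempotent and keeps missing routes when asked", {
  m <- make_mov(rep("2010-03-09 20:00:00", 6),
                mtow_kg = c(78000, 8618, 78000, 9000, 5000, 78000),
                route = c("R1", "R1", NA, "R1", "R1", "R2"))
  once <- filter_flights(m, quiet = TRUE)
  twice <- filter_flights(once, quiet = TRUE)
  expect_identical(twice$flight_id, once$flight_id)
  kept <- filter_flights(m, drop_missing_route = FALSE, quiet = TRUE)
  expect_true(any(is.na(kept$route)))
})

test_that("audibility intervals buffer the correct side and last 600 s", {
  m <- make_mov(c("2010-03-09 23:05:00", "2010-03-09 18:50:00"),
                procedure = c("arrival", "departure"))
  iv <- audible_interval(m)
  expect_identical(iv$start[1], utc("2010-03-09 22:55:00"))
  expect_identical(iv$end[1], utc("2010-03-09 23:05:00"))
  expect_identical(iv$start[2], utc("2010-03-09 18:50:00"))
  expect_identical(iv$end[2], utc("2010-03-09 19:00:00"))
  set.seed(3)
  times <- utc("2010-01-01 00:00:00") + round(runif(25, 0, 365 * 86400))
  iv2 <- audible_interval(make_mov(times,
                                   procedure = sample(c("arrival", "departure"),
                                                      25, TRUE)))
  expect_true(all(as.numeric(iv2$end - iv2$start, units = "secs") == 600))
})

test_that("a buffered flight is attributed to every window it overlaps", {
  # departure at 06:59 is audible 06:59-07:09: inside early morning
  # (06:00-07:00) by overlap, outside it by the point rule
  m <- make_mov("2010-03-10 06:59:00", procedure = "departure")
  w <- windows_for(as.Date("2010-03-10"), "daytime")
  em <- w[w$window_id == "early_morning", ]
  expect_identical(
    noisecross:::flights_in_window(m, em$start_dt, em$end_dt, "overlap"), 1L)
  # touching at a single endpoint does not count: departure at exactly 07:00
  m2 <- make_mov("2010-03-10 07:00:00", procedure = "departure")
  expect_length(
    noisecross:::flights_in_window(m2, em$start_dt, em$end_dt, "overlap"), 0)
  # and an arrival at exactly 06:00 (audible 05:50-06:00) does not reach in
  m3 <- make_mov("2010-03-10 06:00:00", procedure = "arrival")
  expect_length(
    noisecross:::flights_in_window(m3, em$start_dt, em$end_dt, "overlap"), 0)
})
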