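# Decibel arithmetic and the per-event exposure metrics.

test_that("energetic summation combines linear energies", {
  expect_equal(energetic_sum(c(70, 70)), 70 + 10 * log10(2), tolerance = 1e-12)
  expect_equal(energetic_sum(c(70, 70)), 73.0103, tolerance = 1e-4)
  expect_equal(energetic_sum(c(50, 60, 70)),
               10 * log10(1e5 + 1e6 + 1e7), tolerance = 1e-12)
  expect_equal(energetic_sum(c(50, 60, 70)), 70.4532, tolerance = 1e-4)
  for (x in c(-3.2, 0, 55, 91.7)) expect_identical(energetic_sum(x), x)
  expect_identical(energetic_sum(numeric(0)), -Inf)
  expect_error(energetic_sum(c(60, NA)), class = "noisecross_metric_error")
})

test_that("energetic_sum of n equal levels adds 10*log10(n) (scale property)", {
  for (n in c(2, 7, 100, 1000, 10000)) {
    expect_equal(energetic_sum(rep(64.2, n)), 64.2 + 10 * log10(n),
                 tolerance = 1e-9)
  }
})

test_that("L_Aeq normalises by window duration with the zero floor", {
  expect_equal(laeq_from_lae(90, 28800), 90 - 10 * log10(28800),
               tolerance = 1e-12)  # 45.4055 dB over the overall night
  expect_identical(laeq_from_lae(90, 1), 90)  # t0 = 1 s reference
  expect_identical(laeq_from_lae(30, 14400), 0)  # negative -> floored to 0
  expect_identical(laeq_from_lae(-Inf, 3600), 0)  # no flight -> 0
  expect_error(laeq_from_lae(70, 0), class = "noisecross_metric_error")
  expect_error(laeq_from_lae(70, -5), class = "noisecross_metric_error")
})

test_that("the window maximum and NAT follow the zero and strictness rules", {
  expect_identical(lamax_of_event(c(61.2, 58.0, 70.5)), 70.5)
  expect_identical(lamax_of_event(numeric(0)), 0)
  expect_identical(lamax_of_event(55.0), 55.0)
  expect_identical(nat(c(54.9, 55.0, 56.0)), 1L)  # strictly above 55
  expect_identical(nat(c(54.9, 55.0, 56.0), strict = FALSE), 2L)
  expect_identical(nat(numeric(0)), 0L)
  expect_identical(nat(rep(80, 7)), 7L)
  # non-increasing in the threshold
  set.seed(5)
  lv <- runif(50, 40, 80)
  counts <- vapply(seq(40, 80, by = 5), function(th) nat(lv, th), integer(1))
  expect_true(all(diff(counts) <= 0))
})

exposure_setup <- function() {
  # one grid with a known on-receiver value and a one-row movement list
  g <- tiny_grid(matrix(85, 3, 3), matrix(62, 3, 3))
  list(store = footprint_store(list(g)),
       geocode = c(250, 250))  # on a receiver: values exact
}

test_that("an event with no overlapping flight is all-zero but countable", {
  s <- exposure_setup()
  ev <- windows_for(as.Date("2010-03-10"), "daytime")
  ev <- ev[ev$window_id == "evening", ]
  m <- make_mov("2010-03-10 12:00:00")  # noon: outside every night window
  r <- compute_exposure(ev, m, s$store, s$geocode)
  expect_identical(r, list(laeq = 0, lamax_max = 0, nat55 = 0L,
                           n_flights = 0L, n_fallbacks = 0L))
})

test_that("a single flight reproduces the hand-computed metric chain", {
  s <- exposure_setup()
  ev <- windows_for(as.Date("2010-03-10"), "daytime")
  ev <- ev[ev$window_id == "evening", ]  # T = 14400 s
  m <- make_mov("2010-03-09 20:00:00")
  r <- compute_exposure(ev, m, s$store, s$geocode)
  expect_equal(r$laeq, 85 - 10 * log10(14400), tolerance = 1e-12)
  expect_equal(r$laeq, 43.4164, tolerance = 1e-4)
  expect_identical(r$lamax_max, 62)
  expect_identical(r$nat55, 1L)
  expect_identical(r$n_flights, 1L)
})

test_that("adding a flight never decreases any metric (monotonicity)", {
  s <- exposure_setup()
  ev <- windows_for(as.Date("2010-03-10"), "daytime")
  ev <- ev[ev$window_id == "overall_night", ]
  set.seed(9)
  times <- utc("2010-03-09 23:00:00") + sort(round(runif(12, 0, 28700)))
  prev <- list(laeq = -1, lamax_max = -1, nat55 = -1L)
  for (k in seq_along(times)) {
    m <- make_mov(times[seq_len(k)])
    r <- compute_exposure(ev, m, s$store, s$geocode)
    expect_gte(r$laeq, prev$laeq)
    expect_gte(r$lamax_max, prev$lamax_max)
    expect_gte(r$nat55, prev$nat55)
    prev <- r
  }
})

test_that("metrics are invariant under flight reordering", {
  g <- random_grid(13)
  store <- footprint_store(list(g))
  ev <- windows_for(as.Date("2010-03-10"), "daytime")
  ev <- ev[ev$window_id == "overall_night", ]
  set.seed(14)
  times <- utc("2010-03-09 23:05:00") + round(runif(10, 0, 27000))
  m <- make_mov(times)
  geocode <- c(1000 + 333, 2000 + 444)
  base <- compute_exposure(ev, m, store, geocode)
  for (trial in 1:5) {
    perm <- m[sample(nrow(m)), , drop = FALSE]
    r <- compute_exposure(ev, perm, store, geocode)
    expect_equal(r$laeq, base$laeq, tolerance = 1e-12)
    expect_identical(r$lamax_max, base$lamax_max)
    expect_identical(r$nat55, base$nat55)
  }
})

test_that("an unresolvable flight raises a missing-footprint error with its id", {
  s <- exposure_setup()
  ev <- windows_for(as.Date("2010-03-10"), "daytime")
  ev <- ev[ev$window_id == "evening", ]
  m <- make_mov("2010-03-09 20:00:00", route = "R9", flight_id = "F777")
  expect_error(compute_exposure(ev, m, s$store, c(250, 250)),
               regexp = "F777", class = "noisecross_missing_footprint")
  m2 <- make_mov("2010-03-09 20:00:00", aircraft_type = NA_character_,
                 aircraft_group = NA_character_, flight_id = "F888")
  expect_error(compute_exposure(ev, m2, s$store, c(250, 250)),
               regexp = "F888", class = "noisecross_missing_footprint")
})

test_that("the exposure table driver preserves event order and joins geocodes", {
  s <- exposure_setup()
  deaths <- data.frame(person_id = c("P1", "P2"), x = c(250, 0), y = c(250, 0),
                       death_dt = c(utc("2010-03-10 14:30:00"),
                                    utc("2010-03-11 15:00:00")),
                       icd10 = c("I21", "I25"), stringsAsFactors = FALSE)
  ev <- build_events_all(deaths)
  m <- make_mov(c("2010-03-09 20:00:00", "2010-03-10 20:00:00"))
  out <- compute_exposures(ev, deaths, m, s$store)
  expect_identical(nrow(out), nrow(ev))
  expect_identical(out$person_id, ev$person_id)
  expect_identical(out$window_id, ev$window_id)
  expect_true(all(out$nat55 <= out$n_flights))
  expect_true(all(out$laeq_db >= 0) && all(out$lamax_db >= 0))
  # unknown person is an error
  ev_bad <- ev; ev_bad$person_id[1] <- "P9"
  expect_error(compute_exposures(ev_bad, deaths, m, s$store),
               class = "noisecross_event_error")
})
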