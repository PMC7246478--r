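# noisecross

Individual aircraft noise exposure assessment for case-crossover
epidemiological studies.

## What it does, and for whom

Case-crossover studies of acute noise effects compare each subject's
exposure on the night of their health event with the same subject's
exposure on nearby control nights.  That requires an exposure value per
person per night — not an annual average map.  `noisecross` builds that
exposure database for aircraft noise: from an airport movement list,
per-event noise footprint grids, and geocoded death records it computes,
for every case night and every time-stratified control night,

* **L<sub>Aeq</sub>** — equivalent continuous sound level of the window
  (dB),
* **L<sub>Amax</sub>** — highest single-event maximum level in the window
  (dB),
* **NAT<sub>55</sub>** — number of events with L<sub>Amax</sub> > 55 dB.

It is aimed at environmental-epidemiology groups who have (or can
request) an airport's movement lists and an acoustic footprint library,
and want reproducible, per-night exposure metrics at residential
geocodes.

## The method in brief

1. **Events.** Deaths are split by clock time of death: daytime deaths
   (`[07:00, 23:00)`) get five windows of the preceding night — evening
   19:00–23:00, early night 23:00–23:30, core night 23:30–06:00, early
   morning 06:00–07:00, overall night 23:00–07:00 — while nighttime
   deaths get the 2 h preceding death.  Control nights are all other
   same-weekday dates of the same calendar month (3–4 per case,
   bidirectional).
2. **Flights.** Movement lists are cleaned (missing aircraft types
   recovered by tail number and date; only aircraft with MTOW > 8618 kg
   and a known route retained) and each flight carries a 10-minute
   audibility buffer before landing / after departure.  A flight belongs
   to every window its audibility interval overlaps.
3. **Levels.** Each flight's footprint (year × aircraft group × route ×
   procedure; nearest-year substitution when missing) is interpolated at
   the geocode from the 4 nearest receivers by inverse distance
   weighting, `L = (Σ L_i/d_i)/(Σ 1/d_i)`, with the stored value returned
   exactly on a receiver.
4. **Aggregation.** Per window:
   `L_Aeq = 10·log10(Σ 10^(L_AE,i/10)) − 10·log10(T/1 s)` (floored at
   0 dB, also for flight-free windows), `L_Amax = max_i L_Amax,i`,
   `NAT_55 = #{i : L_Amax,i > 55}`.

A seeded synthetic generator (`synth_config()`, `simulate_study()`)
produces footprints, movement lists, a tail registry and death records
with the structural features the method needs (route-to-route nightly
variability, a 23:30–06:00 flight ban, missing-data patterns), so the
full pipeline runs without restricted data.

## Worked example

One footprint (a north–south ridge of levels around route axis "R16"),
three flights around the night of 2010-03-10, one geocode:

```r
library(noisecross)

mk <- function(proc) footprint_grid(
  footprint_key(2010, "NB", "R16", proc),
  origin = c(683000, 246000), cell_size = 250,
  lae   = matrix(95 - 0.8 * abs(row(matrix(0, 9, 9)) - 5), 9, 9),
  lamax = matrix(85 - 0.8 * abs(row(matrix(0, 9, 9)) - 5), 9, 9))
store <- footprint_store(list(mk("departure"), mk("arrival")))

m <- data.frame(
  flight_id = c("F1", "F2", "F3"),
  timestamp = as.POSIXct(c("2010-03-09 21:40:00", "2010-03-09 23:10:00",
                           "2010-03-10 06:20:00"), tz = "UTC"),
  aircraft_type = "A320", tail_number = NA, route = "R16", runway = "RWY28",
  procedure = c("departure", "arrival", "departure"), mtow_kg = 78000,
  aircraft_group = "NB")

ev <- windows_for(as.Date("2010-03-10"), "daytime")
for (i in seq_len(nrow(ev))) {
  r <- compute_exposure(ev[i, ], m, store, c(683400, 246700))
  cat(sprintf("%-14s laeq=%6.2f lamax=%6.2f nat55=%d n=%d\n",
              ev$window_id[i], r$laeq, r$lamax_max, r$nat55, r$n_flights))
}
```

```
evening        laeq= 52.33 lamax= 83.91 nat55=1 n=1
early_night    laeq= 61.36 lamax= 83.91 nat55=1 n=1
core_night     laeq=  0.00 lamax=  0.00 nat55=0 n=0
early_morning  laeq= 58.35 lamax= 83.91 nat55=1 n=1
overall_night  laeq= 52.33 lamax= 83.91 nat55=2 n=2
```

Reading the output: the interpolated per-event level at this geocode is
93.91 dB L<sub>AE</sub>.  The 21:40 departure lands in the evening window
(`T` = 14 400 s, so `laeq = 93.91 − 10·log10(14400) = 52.33`).  The 23:10
arrival is audible from 23:00, so it falls in the short early-night
window, where the same event energy over only 1 800 s gives a higher
L<sub>Aeq</sub> of 61.36 dB.  The core night is flight-free and floored
at zero.  The overall night holds two flights (`nat55 = 2`), but twice
the energy over the full 28 800 s night works out to the same 52.33 dB as
the single evening flight over its shorter window.  Control nights for
this case date are the other Wednesdays of March 2010: 03, 17, 24, 31.

The same pipeline runs from the shell:

```sh
exec/noisecross simulate --out study --seed 1
exec/noisecross sample   --deaths study/deaths.csv --out study/events.csv
exec/noisecross compute  --events study/events.csv \
    --movements study/movements.csv --footprints study/footprints \
    --deaths study/deaths.csv --tail-registry study/tail_registry.csv \
    --group-map study/group_map.csv --out study/exposure.csv
```

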