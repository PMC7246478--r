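---
title: "Assessing individual nighttime aircraft noise exposure for case-crossover studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing individual nighttime aircraft noise exposure for case-crossover studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Case-crossover designs compare a person's exposure just before a health
event with the same person's exposure on nearby reference ("control")
occasions, so each subject acts as their own control and stable personal
characteristics cannot confound the comparison.  Aircraft noise suits this
design unusually well: around airports with multi-directional runway
systems the assignment of traffic to air routes changes from day to day
(wind, operating regime), so the same residence experiences genuinely
different noise from one night to the next.

`noisecross` computes the exposure side of such a study.  Given

1. an airport **movement list** (one row per departure or arrival, with
   timestamp, aircraft type, tail number, air route, procedure, and
   maximum take-off weight),
2. a library of **noise footprints** — regular 250 m receiver grids of
   per-event levels, one grid per (year, aircraft group, route, procedure)
   — and
3. geocoded **death records**,

it attaches three nighttime noise metrics to every case night and every
time-stratified control night of every death:

* **L~Aeq~** — the equivalent continuous sound level of the window,
* **L~Amax~** — the highest single-event maximum level in the window,
* **NAT~55~** — the number of events whose L~Amax~ exceeds 55 dB.

## From a flight to a level at the home address

Each footprint stores, at every receiver, the sound exposure level
L~AE~ (the total A-weighted energy of one fly-over, normalised to 1 s) and
the maximum level L~Amax~.  At an arbitrary residential geocode the level
is interpolated from the **four nearest receivers** by inverse distance
weighting with exponent 1,

$$L = \frac{\sum_{i=1}^{4} L_i / d_i}{\sum_{i=1}^{4} 1 / d_i},$$

with the special case \(L = L_i\) when the geocode falls on a receiver
(\(d_{i,\min} = 0\)).  Two interpolation decisions are deliberate:

* **Interpolation operates on the dB values**, not on energies.  An
  energetic (linear-domain) weighted mean would be defensible physics, but
  the weighted mean of levels is the procedure the method defines, and on
  250 m grids with smooth footprints the difference is small.
* **"Four nearest" means the four receivers with smallest Euclidean
  distance**, not the four corners of the enclosing cell.  The two
  readings coincide for interior points and differ only along grid edges,
  where the nearest-receiver reading degrades more gracefully.
* Distances below 10^-6^ m are treated as zero, so a geocode placed
  exactly on a receiver by rounding still returns the stored value.

A geocode outside a footprint's extent raises an error rather than
extrapolating; study-area selection should make this impossible, and a
silent extrapolation would be worse than a loud failure.

Footprints are year-specific, and not every (group, route, procedure,
year) combination exists.  A missing footprint is substituted by a similar
one from a different year: first the nearest other year within the same
time-of-day stratum (ties resolved toward the earlier year, for
determinism), then the nearest year ignoring the time-of-day stratum.
The route is never substituted — a footprint for a different route is a
different noise geography, not a "similar" footprint.  Every substitution
is reported with both keys.

## Flights, audibility and windows

The movement timestamp is the moment of touch-down or brake release, but
residents farther from the airport hear the aircraft before landing and
after take-off.  Each flight therefore carries a **10-minute audibility
interval**: `[t − 10 min, t]` for arrivals, `[t, t + 10 min]` for
departures.  A flight belongs to an exposure window when its audibility
interval overlaps the window with positive measure (half-open logic:
touching at one endpoint does not count).  A flight straddling an internal
window boundary contributes its full event energy to both windows — the
footprints are per-event, not time-resolved, so splitting the energy is
not possible; this is a known, documented approximation.  The alternative
point rule (raw timestamp inside the window) is available via
`membership = "point"`.

Movement lists are cleaned before use: missing aircraft types are
recovered from a tail-number registry (tail number + flight date →
registered type; present types are never overwritten), then only **large
aircraft (MTOW strictly above 8618 kg)** with a known air route are
retained.  Small-aircraft traffic is negligible at night, and a flight
without a route cannot be matched to a footprint.

Deaths are split by clock time: **daytime deaths** (`[07:00, 23:00)`)
receive five fixed windows of the preceding night,

| window | clock span | T (s) |
|---|---|---|
| evening | 19:00–23:00 | 14 400 |
| early night (delayed flights) | 23:00–23:30 | 1 800 |
| core night (flight ban) | 23:30–06:00 | 23 400 |
| early morning | 06:00–07:00 | 3 600 |
| overall night | 23:00–07:00 | 28 800 |

all anchored so the night block ends at 07:00 on the event date;
**nighttime deaths** (`[23:00, 07:00)`) receive a single 2-hour window
ending at the death clock time, to probe short-latency triggering.  All
windows are half-open `[start, end)`; the three sub-windows partition the
overall night exactly.  Control nights for a nighttime death reuse the
case's death clock time, so case and control windows have identical
duration — without this the L~Aeq~ normalisation would differ mechanically
between case and control.

Control dates follow the **time-stratified referent scheme**: every other
date in the same calendar month falling on the same weekday, which yields
3 or 4 bidirectional controls for every possible case date.

All timestamps are naive local clock times; windows are nominal clock
intervals and daylight-saving transitions are ignored (flight timestamps
are clock times too, so both sides of every comparison shift together).
On the two transition nights per year the true elapsed duration of a
window differs from its nominal `T` by up to one hour; this approximation
is accepted deliberately.

## Aggregation

Within a window the per-flight L~AE~ values are summed energetically,

$$L_{AE,\mathrm{tot}} = 10 \log_{10} \sum_i 10^{L_{AE,i}/10},$$

and converted to the equivalent continuous level with the window duration
\(T\) (seconds, reference \(t_0 = 1\) s):

$$L_{Aeq} = L_{AE,\mathrm{tot}} - 10 \log_{10}(T / t_0).$$

Windows with no flight, and windows whose L~Aeq~ comes out negative, are
set to **0 dB**.  The zero rule is extended to the other two metrics
(empty maximum → 0 dB, empty count → 0), and `n_flights` is reported
alongside so an analyst can always distinguish true silence from a floored
value.  `log` is log~10~ throughout — decibel arithmetic admits no other
base.  Accumulation happens in the energy domain in double precision;
nothing is rounded until CSV output (3 decimals).

NAT uses a strict inequality (a flight at exactly 55.0 dB is not counted);
`nat_strict = FALSE` switches to ≥ for sensitivity analyses.

## The synthetic study generator

The restricted inputs (a national cohort extract and an airport's movement
lists) cannot ship with a package, so `synth_config()` +
`simulate_study()` generate a complete synthetic study with the structural
features the method relies on:

* **Footprints** with a toy monotone decay away from the route axis,
  `L_AE(x) = source_level − k·log10(1 + d/d₀)` (defaults k = 22,
  d₀ = 300 m, L~Amax~ = L~AE~ − 10 dB), on the package's 250 m grid.  The
  source levels (98–103 dB for the heavy groups) were chosen once so that
  simulated overall-night L~Aeq~ values span roughly 20–75 dB near and far
  from the routes — the order of magnitude seen around a major airport —
  and are a qualitative calibration only.
* **Movements** with Poisson nightly counts (default mean 30), a per-night
  route regime resampled from Gamma weights (a weather proxy, so the same
  geocode sees different exposure across nights), a 23:30–06:00 flight ban
  with occasional delayed flights displaced into 23:00–23:30, and
  configurable fractions of missing aircraft types (recoverable or not via
  the generated tail registry), missing routes, and light aircraft — so
  every cleaning and error path of the pipeline is exercised by
  construction.
* **Deaths** uniform over the region and study span, with a configurable
  day/night mix (default 2/3 daytime) and ICD-10 codes from I00–I99.

Each generator draws from its own substream derived from the master seed,
so footprints, movements and deaths can be regenerated independently and
the whole pipeline is byte-stable for a given configuration.

What the generator does **not** emulate: real route geometry and fleet
mix, lateral dispersion of trajectories around the route axis, topography
and meteorological propagation effects, seasonal schedules, and spatial
clustering of residences.  Tests passing on synthetic data therefore
demonstrate the correctness of the exposure *arithmetic and bookkeeping*,
not the acoustic realism of any particular footprint library.

## Numerical and design notes

* Interpolated levels are bounded by their four neighbour values, and the
  interpolant is continuous except exactly at receivers, where the exact
  stored value takes over.
* Tie-breaks (equidistant receivers, equidistant fallback years) are
  deterministic: row-major receiver order, earlier year.
* Degenerate inputs fail loudly with classed conditions
  (`noisecross_parse_error`, `noisecross_extent_error`,
  `noisecross_missing_footprint`, …) carrying the offending file line,
  key, or flight id.
* The test suite and the bundled acceptance script run the pipeline at
  desk scale — one study year, a 20 × 20 km region, tens of deaths,
  ~10^4^ movements — which exercises every code path in a few seconds
  while keeping the package light.  All sizes scale up linearly through
  `synth_config()`.

## Limitations

* Exposure is outdoor exposure at the residential geocode; time spent away
  from home, window orientation and insulation are epidemiological
  adjustments outside this package's scope.
* The package stops at the exposure database.  The downstream conditional
  logistic regression of the case-crossover analysis is intentionally not
  included.
* No coordinate transformations: all inputs must share one projected
  metric CRS.
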