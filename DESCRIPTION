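Package: noisecross
Title: Individual Aircraft Noise Exposure Assessment for Case-Crossover
    Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes individual nighttime aircraft noise exposure at
    residential geocodes for case-crossover epidemiological studies.  From
    an airport movement list, per-event noise footprint grids (sound
    exposure level L_AE and maximum level L_Amax on a regular 250 m
    receiver grid) and geocoded death records, the package derives the
    equivalent continuous sound level (L_Aeq), the maximum event level
    (L_Amax) and the number of events above a 55 dB threshold (NAT_55) for
    a set of nighttime exposure windows, for case nights and
    time-stratified control nights matched on weekday within calendar
    month.  Includes inverse-distance-weighted interpolation of footprint
    grids, footprint fallback substitution, movement-list cleaning and
    filtering, exposure-window construction, and seeded synthetic
    generators for footprints, flight schedules and death records so the
    full pipeline runs without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
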