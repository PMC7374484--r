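# rfidtrack

Grid-based passive RFID localization and activity estimation for
group-housed birds.

## The problem

Broilers are kept in groups, which makes monitoring the behaviour of
*individual* birds hard: video gives positions but not identities, and
active tags (UWB) are too heavy for chicks. A passive HF RFID floor grid —
lightweight leg tags read by antennas under the litter — identifies every
bird from the day of hatching, but it localizes only to the antenna
rectangle the tagged leg is over, registers poorly when birds lie down, and
flickers when a tag sits on the boundary between two antennas.

`rfidtrack` implements the full methodology for turning such registration
logs into validated location and activity measures:

* **Grid geometry** — antenna centres, straight-line centre-to-centre
  distances, Moore (8-neighbour) adjacency. The minimum centre distance
  (36 cm on the default 5 × 6 grid covering a 1.8 × 2.6 m pen, antenna 7
  dead) defines one *switch unit*; a move between antennas `a` and `b`
  counts `d(a,b) / 0.36` units, and units convert to metres by 0.36. A
  vertical within-panel move of 45 cm, for instance, is 1.25 switches.
* **Log handling** — parsing/writing delimited registration logs, a
  forward-fill ("last known position") completion for second-by-second
  location comparison, data-completeness screening (exclusion below 75% of
  scheduled hours with data), and the five-second false-switch filter: a
  switch into an antenna that was already registered less than 5 s earlier
  is a boundary bounce and is removed together with its matching outbound
  switch, so a stationary bird flickering between two antennas nets zero
  distance.
* **Activity estimation** — per-period totals of switch units and metres
  and duration-corrected hourly rates.
* **Location validation** — cleaning of ground-truth annotation streams,
  per-second alignment, and exact / near match percentages (near = within
  one antenna, i.e. any of up to eight Moore neighbours).
* **Agreement statistics** — Fleiss' and Cohen's kappa for observer
  reliability, Spearman rank correlation with seeded percentile-bootstrap
  CIs, and repeated-measures correlation (ANCOVA with subject as factor and
  common slope, `df = N − k − 1`).
* **A synthetic pen** — a correlated-random-walk movement model with
  rest/active bouts and posture, plus three observers (the RFID grid with
  posture-dependent detection and boundary flicker, a centre-point video
  observer with a half-body-width movement threshold, and a UWB-style
  observer sampling noisy positions every 6.91 s), so the entire pipeline
  is testable without farm data.

## Worked example

Simulate a 6-bird half-hour pen with every sensor, validate locations
(study A) and distances (study B):

```r
library(rfidtrack)

cfg <- sim_config(n_birds = 6, duration = 1800, seed = 11)
bundle <- make_bundle(cfg)

run_study_a(bundle)$report
#> Location match report: 9165 included registrations (1635 excluded)
#>   exact matches: 8095 (88.3%)
#>   near matches:  9151 (99.8%)

b <- run_study_b(bundle, n_boot = 1000, seed = 11)
round(b$distances[, c("rfid", "video", "uwb", "truth")], 2)
#>    rfid video   uwb truth
#> 1  8.36  8.90 78.31  8.92
#> 2 11.17 12.81 78.94 12.84
#> 3  1.51  2.35 71.20  2.40
#> 4  6.47  7.19 73.90  7.19
#> 5 15.59 16.13 80.52 16.20
#> 6  5.31  5.89 72.29  5.90
b$correlations$rfid_video
#> Spearman rank correlation: 1.000 (95% CI 1.000 to 1.000), n = 6, p = 0
```

The reading: nearly every second-by-second location agrees within one
antenna; the RFID distance is a systematic *underestimate* of the video
distance (within-antenna movement is invisible to the grid); the UWB
distance is a large *overestimate* for these mostly resting birds (its
positional noise alone contributes ~0.27 m per 6.91-s sample); and all
three sensors agree on which birds are the active ones — the quantity the
method is designed to recover.

Registration logs, schedules, grid configurations and all report tables
read and write as plain delimited text / YAML (`read_rfid_log()`,
`read_grid_config()`, `write_bundle()`, ...), so the same pipeline runs on
real log files.

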