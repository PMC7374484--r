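---
title: "Grid-based RFID activity tracking: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grid-based RFID activity tracking: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rfidtrack)
```

This vignette is the package's own account of the method it implements: how
a floor grid of passive RFID antennas is turned into per-bird locations and
locomotor activity, how those outputs are validated against independent
observers, and which modelling and numerical decisions were open — and how
they were settled.

## 1. The measurement model

A passive HF tag on a bird's leg is read, at 1 Hz, by whichever antenna
rectangle the tag is over. The log is therefore a sequence of
`(time, tag, antenna)` registrations on a discrete spatial support. Two
derived quantities matter:

**Location.** For second-by-second comparison with a ground-truth stream,
missing seconds are completed by the *last-known-position* rule: a tag not
registered elsewhere is assumed still to be at the antenna of its most
recent registration (`fill_forward()`). Seconds before the first
registration stay missing. This completion is used *only* for location
validation; distance estimation works on the raw switch sequence, where a
gap simply contributes no movement.

**Distance.** Movement is observed only as *antenna switches*. Each switch
is valued at the straight-line centre-to-centre distance between the two
antennas, expressed in *switch units* — multiples of the grid's minimum
centre distance (0.36 m by default) — and converted to metres by that same
unit. Two error sources are inherent and deliberately not compensated:
within-antenna movement contributes zero, and the straight line is a lower
bound on the path actually walked between two antennas. The estimate is
designed to rank individuals by activity, not to measure absolute distance.

### The false-switch (bounce) filter

A tag resting on the boundary between two antennas can be read by both,
producing alternating registrations that mimic locomotion. The filter rule:
a switch into antenna $X$ at time $t$ is a *bounce return* if $X$ was also
registered, in the original unfiltered stream, strictly less than `window`
(default 5) seconds before $t$. A bounce return is excluded; when the
immediately preceding surviving switch was the matching move out of $X$, it
is excluded with it. Implementation is a stack collapse over the run-length
encoded registration sequence: each surviving switch pushes the new
antenna; a paired bounce pops the excursion. Consequences worth knowing:

* sustained 1 Hz flicker between two antennas nets exactly zero switches
  (`A,B,A,B,A,B` at 1-s spacing collapses completely);
* a bounce return whose partner switch is already gone (as happens from the
  second flicker cycle onward, or after a multi-antenna excursion) is
  dropped alone — this keeps the surviving switch sequence a connected
  walk, which the tests assert;
* genuine sub-5-s round trips are also removed. That is the filter's cost,
  accepted because a stationary boundary bird *must* net zero distance.
* the lookback is an open interval $(t - 5, t)$, matching a strict
  "less than five seconds" reading; a return exactly 5 s after the previous
  registration at that antenna survives.

When a recording schedule is supplied, streams are filtered per recording
interval, so a switch spanning a handling gap (weighing, leg-band checks)
is discarded — positions may have been moved by humans during the gap.

### Validation statistics

Locations are compared per (individual, second) over the rows where both
streams are observed; rows with either side missing are excluded and
counted. An *exact* match is the same antenna; a *near* match allows a
deviation of one antenna, defined as Chebyshev distance ≤ 1 in grid
indices (the Moore neighbourhood, at most eight antennas) — not as a
centre-distance threshold, which would treat the 42/45 cm vertical pitches
asymmetrically. Ground-truth annotation streams are cleaned first:
out-of-grid and dead-antenna annotations become missing, and a
*single-frame* excursion to an antenna non-adjacent to the preceding
retained frame is treated as an annotation error and blanked. Two-frame
excursions are kept, and the first frame can never be declared a jump.

Distance agreement uses Spearman rank correlations (the distances are not
normally distributed) with percentile-bootstrap 95% CIs over paired
resampling (default 1000 resamples, seeded); ties get average ranks.
Repeated measurements of the same birds across days are handled by the
repeated-measures correlation: ANCOVA of $y$ on subject (factor) plus a
common slope for $x$, with
$r_{rm} = \mathrm{sign}(b)\sqrt{SS_x / (SS_x + SS_{err})}$ on
$N - k - 1$ degrees of freedom, CI via the Fisher $z$ transform with
standard error $1/\sqrt{df - 1}$. Linearity and normal errors are assumed
but not enforced; the implementation reports, it does not gate. Observer
reliability uses Fleiss' kappa (many raters) and unweighted Cohen's kappa
(paired ratings), both with large-sample null variances for the $Z$ test
and an explicit `degenerate` flag when expected agreement is 1 (kappa
undefined) — degenerate inputs return a flagged result, never `NaN`.

## 2. The grid model

The default grid reproduces a 1.8 × 2.6 m pen fully covered by 30 antennas
of 32 × 41 cm mounted pairwise on fifteen panels: 5 columns at 0.36 m
pitch, 6 rows alternating 0.45 m (within a panel) and 0.42 m (across
panels), so that $5 \times 0.36 = 1.80$ m and
$3 \times 0.45 + 2 \times 0.42 + 0.41 = 2.60$ m close the pen exactly.
These pitches reproduce every printed geometric quantity — the 36 cm
minimum centre distance, the 45 cm pair worth 1.25 switch units, the
4.7 m² pen — but the exact within- vs between-panel spacings are an
inference from the antenna and pen dimensions, so all pitches are
configuration fields, not constants. Likewise antenna numbering: the
default is row-major, 1-based from the origin corner, and configurable,
because any corner could equally be antenna 1. Antenna 7 is dead by
default; dead antennas keep full geometry (centres, distances,
neighbourhoods — needed for near-match logic) but never emit
registrations.

Numerical conventions: coordinates in metres with the origin at a pen
corner; antenna rectangles are half-open (left/bottom edge inclusive) so
`antenna_at()` is single-valued on edges; points in the uncovered gaps
between rectangles map to missing, which is a valid return, not an error.

## 3. The synthetic pen

No farm data ship with the package, so `synthetic_data` provides the study
conditions: ground-truth trajectories plus the three observers, all
deterministic given `(config, seed)`.

**Movement** is a two-state process per bird: rest bouts end with
per-second probability `p_rest_to_active` × an individual lognormal
activity multiplier (`sdlog` 0.6), activity bouts end with probability
`p_active_to_rest`; while active the bird performs a correlated random
walk (gamma step lengths, mean `speed_mean`; Gaussian heading increments,
sd `turning_sd`) reflected at the walls. Resting birds lie for 80% of
bouts (`standing_idle_fraction` 0.2) and do not turn. Defaults —
0.005/s, 0.08/s, 0.10 m/s, 0.4 rad/s — give an active fraction around 6%,
stable individual differences, and hourly distances of roughly 2–60 m
across a flock, the realism target for a mostly-resting broiler pen whose
video-measured distances span tens of metres per hour. `turning_sd` is
0.4 rad/s (heading persistence of a few seconds) because broilers walk in
directed bouts; per-second Brownian-like heading produces boundary
dithering that no real bird shows and that corrupts the
switch-quantized distance estimate upward.

**The tagged leg** sits a per-bird distance (`leg_offset`, default 5 cm)
from the body centre in a fixed per-bird direction. The direction is fixed
deliberately: the leg then travels exactly as far as the body while still
often sitting in a different antenna cell, which is the real mechanism
behind centre-vs-leg location mismatches. (An earlier model iteration
rotated the offset with the heading; that adds spurious leg travel of
order `offset × |turn rate|` per second and is an artifact, not a
mechanism.)

**The RFID observer** reads the antenna under the leg each second with
probability 0.95 (standing), 0.5 (walking) or 0.05 (lying). The lying rate
is low because a lying tag is parallel to the antenna plane and barely
couples. The walking rate is intermediate because the read field is only
~10 cm deep and a walking leg swings through it, so briefly visited
antennas can go unrecorded — without this, a walking bird is tracked
nearly perfectly cell-by-cell and the axis-aligned staircase of visited
centres systematically *exceeds* the true path length, inverting the
under-estimation that defines the real system. Within 3 cm of an edge
(`boundary_band`), a *standing* tag is registered at the flanking antenna
with probability 0.2 per read (occasionally both in one second) —
flicker is a stationary-tag phenomenon; walking and lying tags do not
alternate. Dead antennas, and optionally a degraded zone after an onset
time (emulating moisture under a drinker), never register.

**The video observer** annotates the antenna under the *body centre*
(plus 2 cm Gaussian annotation jitter) — not the leg — reproducing the
reference-point mismatch between video and RFID. Its distance measure
emulates circle-based video tracking: nothing is counted until the centre
leaves a circle of half a body width (6 cm) around its anchor; from then
the full path is accumulated until the bird stops, when the circle is
re-placed. Sub-threshold idle drift is the only loss.

**The UWB observer** samples the body centre every 6.91 s with isotropic
Gaussian noise (sd 0.15 m) and sums consecutive displacements. For a
stationary tag the expected total is $(n-1)\,\sigma\sqrt{\pi}$ over $n$
samples — each step is the norm of a difference of two independent
bivariate normals, i.e. Rayleigh with scale $\sigma\sqrt{2}$ — and the
tests hold the simulated value to that closed form within 5%. This noise
term is why UWB distances exceed RFID distances for essentially every
bird-period in the simulation, the direction the real comparison shows.

What the generator does *not* emulate: feeding/drinking behaviour and
social interaction, diurnal rhythms, age-related activity decline and
body growth, tag loss, or RF physics beyond the per-posture read
probabilities. Passing tests therefore demonstrate that the *pipeline*
recovers what the simulated sensors encode under these mechanisms — not
that any particular real installation meets the same read probabilities.

## 4. Problem sizes and test design

The validation experiments in the test suite run at desk scale, chosen to
keep the full suite under a minute while leaving clear statistical
margins: direction-of-bias checks use three replicate 30-bird one-hour
pens (90 bird-hours), activity-rank recovery uses twenty replicates of 25
birds × 1 h, and the repeated-measures correlation recovery uses 100
replicates of 25 subjects × 18 repeats at a true within-subject
correlation of 0.7. Statistics are verified to 1e-12 against brute-force
oracles implemented independently in the test code (explicit pairwise
agreement counting for Fleiss, marginal products for Cohen, rank-formula
Spearman). Scripted-waypoint trajectories bypass all randomness where an
exact identity is asserted — a noiseless world must give 100% exact
matches and metre-exact distances on centre-to-centre walks with
super-window dwells.

## 5. Known limitations

* The distance estimator cannot see within-antenna movement and undercounts
  curved inter-antenna paths; it is a relative-activity instrument.
  Conversely, slow shuffling back and forth across one boundary with
  dwells longer than the filter window is over-counted at 0.36 m per
  crossing; the five-second window trades these two errors.
* The completeness criterion's denominator ("scheduled hours containing at
  least one registration") is one reasonable reading of a <75%
  data-availability rule; it is robust to lying-down non-detection within
  an hour but coarser than a per-second accounting.
* The bounce filter removes genuine sub-window round trips, and its
  unpaired branch drops a return switch without a partner; both are
  documented behaviour, not bugs.
* `rmcorr()` assumes a common within-subject slope; heterogeneous slopes
  bias it toward zero. The bootstrap CI for Spearman uses the percentile
  method only.
* Simulation defaults are invented where no measurement exists (read
  probabilities, flicker rate, movement parameters); every one is a config
  field, and conclusions that depend on them should be re-checked across a
  plausible range.
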