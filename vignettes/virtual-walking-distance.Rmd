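---
title: "Virtual walking distances from RFID reading streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual walking distances from RFID reading streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(penwalk)
library(data.table)
```

## The measure

Group-housed fattening pigs cannot carry leg- or collar-mounted sensors, so
their walking activity is hard to quantify at the individual level. When a
pen's functional areas — feeding trough, nipple drinkers, an enrichment
("playing") device — are each equipped with a UHF-RFID antenna, every
ear-tagged pig produces a stream of timestamped detections: at most one
reading per second per antenna while the pig is inside that antenna's
reading area.

The **virtual walking distance** (VWD) turns this stream into a daily
activity measure. Let $\ell_1, \ell_2, \dots, \ell_k$ be the sequence of
*distinct* antenna locations an animal visits during one calendar day
(consecutive readings at the same antenna are one visit), and let
$d(\cdot,\cdot)$ be the planar Euclidean distance between antenna center
points. Then

$$\mathrm{VWD} = \sum_{i=1}^{k-1} d(\ell_i, \ell_{i+1}).$$

Because a pig must physically move from one reading area to the next to
produce consecutive readings at different antennas, and because straight
lines are shortest, the VWD is a *lower bound* proxy for the distance
actually walked — it sees none of the wandering between or around antennas.
The one caveat is the horizontal extent of a reading area: a pig detected at
the edge of two large reading areas travels slightly less than the
center-to-center distance, which is why the measure is called "virtual"
rather than "minimum". Collapsing same-antenna runs is mathematically
optional ($d(x,x) = 0$), but the package does it explicitly and tests that
both routes agree.

Since $d$ is a metric, deleting readings from a day can never increase the
VWD (triangle inequality). This *subsampling monotonicity* is the key
robustness property: imperfect per-second detection sensitivity (around 0.9
at the trough, 0.6 at the drinkers, 0.75 at the playing device in the kind
of installation emulated here) biases the measure downward but cannot
inflate it. `validate_distance_matrix()` therefore checks the triangle
inequality exhaustively over all ordered location triples before a matrix is
accepted into a `pen_layout`.

## Conventions and numerical choices

Several choices are genuinely open; the package fixes them as follows.

* **Day boundary.** Each calendar day is computed in isolation: the first
  reading of a day opens a new path and no transition spans midnight.
  Overnight transitions would mostly bridge the nocturnal rest phase
  (roughly 22:00–06:00, when the feeding system is idle and the lights are
  off) and are both rare and ambiguous to time.
* **Hour binning.** `hourly_vwd()` assigns each transition's distance to the
  hour of the *arriving* visit's first detection — the latest defensible
  time at which the movement was complete. Bin `h00` covers midnight to
  1 a.m. The 24 bins always sum to the daily total (asserted to 1e-9 m).
* **Missing is not zero.** A pig-day with no readings yields no row, and an
  empty input yields `vwd_m = NA`: absence of detections is missing data
  (validation phases, hardware outages), not evidence of immobility. A
  single detection, however, is enough for the day to count — there is no
  minimum visit duration, because brief pass-bys carry distance information.
* **Same-second readings at two antennas** are physically dubious but kept,
  ordered by location id; silently dropping data would hide sensor issues,
  and run-collapsing bounds their effect.
* **Fattening stages** are closed bins over fattening days (move-in day
  = day 1): 1–30, 31–60, 61–90, >90 by default, configurable via
  `stage_breaks`.
* **Stage means** come in two descriptive variants: over all pig-days
  (`all_days`) and over per-pig stage means (`per_pig_means`). They coincide
  exactly under balanced designs and diverge toward over-represented pigs
  otherwise; both are plain unweighted arithmetic means, and no inferential
  statistics are attached.
* **Timestamps** are naive local clock time processed in a fixed UTC frame:
  no timezone or DST arithmetic. This is a documented limitation, adequate
  for barn loggers on a local wall clock.
* **Precision.** Distances are carried at full double precision everywhere;
  the 0.1 m granularity of published distance tables is a display
  convention only. The triangle-inequality and matrix-consistency checks use
  a 1e-9 m tolerance to absorb floating-point error; coordinate-derived
  versus explicit matrices are compared at 0.05 m, matching the print
  precision of the bundled matrix.

## The worked minimal day

The least active days observable in this kind of pen are pigs detected only
at the trough, then the playing device, then the trough again. With the
bundled five-location matrix (trough–playing device = 5.2 m):

```{r}
lay <- table2_layout()
rd <- data.frame(
  animal_id = "pig_min",
  timestamp = as.POSIXct("2016-09-15 00:00:00", tz = "UTC") +
    c(7, 12, 18) * 3600,
  location_id = c("trough", "playing_device", "trough"))
daily_vwd(rd, lay)
```

5.2 + 5.2 = 10.4 m — the floor of the measure for a day with any
inter-antenna movement at all in this pen geometry.

## The synthetic barn

Real reading streams from instrumented barns are not publicly
distributable, so the package ships a simulator whose output has exactly the
statistical structure the analysis assumes, plus the ground truth the real
system can never provide. It is explicitly an artifact construction: no
distributional description of real pig visits backs it, and it should be
read as "data shaped like the problem", not as a behavioral model of pigs.

One pig-day is a renewal (semi-Markov) trajectory over the pen locations
plus an implicit resting state:

1. Visit start times follow an inhomogeneous Poisson process. The hourly
   intensity is a base rate shaped by three factors: a boost (default 1.9)
   in the hour following each feeding start (defaults 06:00, 09:00, 12:00,
   15:00, 18:00, 22:00 — six feedings, the last at 10 p.m.), an elevated
   late afternoon/evening (default 1.6 over 16:00–21:00), and strong
   suppression (default 0.05) in the nocturnal rest window 22:00–06:00.
2. Visit locations are drawn from fixed preference weights (trough 0.35,
   drinkers 0.15 each, playing device 0.20); dwell times are exponential
   (means 25 s trough, 10 s drinkers, 15 s playing device), truncated so
   visits never overlap or cross midnight, minimum 1 s. Movement between
   locations is instantaneous at the reading level — detections only happen
   inside reading areas — so transit time is folded into rest.
3. Activity scales multiplicatively: a per-pig lognormal multiplier
   (median 1, log-sd 0.35), a per-stage multiplier (defaults 1.0 / 0.8 /
   0.6 / 0.5 across the four stages, encoding the decline of activity over
   fattening), and an optional lameness factor (e.g. 0.3 during an episode).
4. Detection thins every whole visit-second independently with the
   location's sensitivity (defaults 0.9 trough / 0.6 drinkers / 0.75
   playing device).

The expected visit count for a unit-multiplier stage-1 pig,
`visits_per_day = 78`, was set once from the pen geometry: with the default
location weights the mean distance per drawn transition is about 3.7 m, so
typical simulated days land around 280 m and the cohort spans roughly
10–800 m per day across pigs and stages — the range such installations
observe. These constants live in `sim_scenario()` arguments, not in code.

The ground-truth table records each pig-day's true center-path length (over
*all* visits, detected or not). Two properties connect truth and
measurement, and both are asserted in the test suite:

* at sensitivity 1.0 every visit-second is read, so the computed VWD equals
  the ground-truth path length exactly (bit-for-bit: the two sums traverse
  the same distances in the same order);
* under any dropout the detected sequence is an order-preserving subset, so
  VWD ≤ truth on every pig-day, with paired replays (the per-pig/per-day
  RNG substreams depend only on the root seed, not on the sensitivities)
  showing element-wise monotonicity.

The bundled pen coordinates are a least-squares planar embedding of the
published distance matrix, frozen in the fixture (maximum deviation
0.014 m, within the matrix's 0.1 m print precision); the simulator's ground
truth uses matrix distances directly, so the exact embedding is immaterial.

Health records emulate twice-weekly inspections (fattening days 1, 4, 8,
11, ...): locomotion score 0 outside lameness events, 2 in the first half
of an event and 1 in the second, mirroring onset and partial recovery.

### What passing tests do and do not show

The simulator reproduces the *structural* features the pipeline relies on —
1 Hz potential detections, per-location sensitivity, feeding-driven diurnal
rhythm, nocturnal rest, stage decline, pig-level heterogeneity, lameness
drops — but not social behavior, spatial continuity of movement,
reading-area geometry or overlap, feed intake, or seasonal effects. Tests
passing on simulated cohorts therefore validate the computation and its
invariants, not any claim about real barns; cohort-level numbers from real
installations (stage means near 283/234/164/144 m, hourly peaks around
20–32 m) serve only as qualitative range and ordering checks on defaults.

## Problem sizes in the test suite

The suite exercises: 1,000 random sequences (lengths 0–500) against a
brute-force pairwise-sum oracle; 200 random sequence/subset pairs for
subsampling monotonicity; a 10 × 30 cohort (300 pig-days) for hour-bin
conservation; a paired 10 × 15 cohort for the ground-truth equality and
dropout monotonicity; a 25 × 120 default cohort (3,000 pig-days, ~3 million
readings) for stage-decline and diurnal recovery; and a 3 × 60 cohort with
one injected lameness event (factor 0.3, 14 days) for the activity-drop
signature. These sizes make every distributional check comfortably
significant while keeping the whole suite under a minute on one core.

## Limitations

* The VWD is not the distance walked; the gap to the true distance is
  unassessable from RFID alone and grows with the fraction of the pen
  uncovered by reading areas.
* No lameness *detector* is included — the health overlay is descriptive,
  and thresholding VWD drops into alarms is future work.
* Naive local time; no DST handling.
* The simulator's semi-Markov assumption is untested against real visit
  logs and is labelled as such.
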