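---
title: "Models and conventions behind lickometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and conventions behind lickometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lickometry)
```

`lickometry` is two artifacts in one package: a digital twin of an
RFID-gated, volumetrically metered sipper device for group-housed rats,
and the analysis library for the CSV logs such a device produces. This
vignette documents the models, conventions and numerical choices, and
what the simulation-based tests do and do not establish about real data.

## The behavioural model

Each rat is described by a `rat_behavior()` row. Drinking events
("bouts") are initiated by an inhomogeneous Poisson process whose rate
is `bout_rate_dark` (bouts/h) during the dark phase and
`bout_rate_light` during the light phase. This is the simplest process
that reproduces the two dominant features of rodent home-cage drinking:
strong dark-phase concentration of intake, and session-level bout
counts that fluctuate Poisson-like around a stable mean. It deliberately
omits temporal correlations (prandial drinking, post-bout refractory
behaviour beyond the firmware gap, meal clustering), so simulated logs
are a *calibration standard* for the analysis chain, not a behavioural
claim.

Each bout independently targets the ethanol spout with probability
`ethanol_choice_p`; its lick count is lognormal
(`lick_count_logmean`, `lick_count_logsd`, rounded to an integer ≥ 1);
its lick train has i.i.d. gamma inter-lick intervals with mean
`interlick_mean_s` and shape `interlick_shape`.

Defaults (chosen once as realistic study conditions, and used by the
test suite and the acceptance script):

| parameter | default | unit | rationale |
|---|---|---|---|
| `bout_rate_dark` | 5 | bouts/h | ~75 drinking events/day, ~30 mL/day total fluid for a 300 g rat |
| `bout_rate_light` | 1.25 | bouts/h | 4:1 dark:light drive → ~80% dark-phase intake |
| `ethanol_choice_p` | 0.7 | — | a preferring but not exclusive drinker; `default_behaviors()` spreads 0.50–0.85 across rats to emulate individual differences |
| `lick_count_logmean` | log 70 | — | median 70 licks/bout; <2% of bouts fall below the 20-lick analysis threshold |
| `lick_count_logsd` | 0.6 | — | right-skewed bout sizes spanning the default lick-range bins |
| `interlick_mean_s` | 0.15 | s | rats lick rhythmically at roughly 6–7 Hz |
| `interlick_shape` | 20 | — | CV ≈ 0.22, a regular but not metronomic rhythm |

## The firmware model

The device grants the spout to one animal at a time. The simulator
enforces this with a busy-until ledger per device (and per rat — an
animal cannot drink at two spouts at once): an attempt that finds the
spout busy is retried after an exponential delay (`retry_mean_s`,
default 30 s), up to `max_retries` (default 3) times, then dropped.
Dropped and deferred attempts are recorded in the ground truth, so tests
can verify that logged bouts are a subset of intended bouts. A bout ends
when no lick occurs for `bout_gap_s` (default 10 s); the same gap
defines bout segmentation when analysing lick-level logs, so the two
sides of the package agree on what one logged row means.

The pump is a stepper-driven peristaltic: `steps_per_lick` motor steps
(default 5) are issued per detected lick, each nominally delivering
`pump_uL_per_step` µL (default 1.0 µL — a calibration constant, not a
hardware datum). Actually delivered per-step volume is multiplied by
i.i.d. Normal(1, `pump_noise_cv`) noise truncated at zero
(default CV 0.15, set so that the 20-trial 1.00 mL bench protocol
yields mean absolute errors of a few tenths of a percent, the scale
this class of device achieves). The device *meters* volume as
steps × µL/step; `simulate_dispense_test()` steps until the metered
volume first reaches the target, so with zero noise the per-trial error
is pure quantization, bounded by one step's volume over the target.

Reproducibility: all stochastic draws flow from one seeded generator in
a fixed order (per rat: segment bout counts, bout times, fluid choices,
lick counts, lick trains; then retry delays in event order; then pump
noise in chronological bout order). Identical parameters and seed give
byte-identical log files.

## Time conventions

* Timestamps are POSIXct in UTC; no timezone or daylight-saving
  handling beyond the fixed light-cycle anchor.
* Zeitgeber time: ZT0 is the lights-on instant, the standard
  chronobiology convention, so lights-on = lights-off + `dark_hours`
  and the dark phase spans ZT `24 − dark_hours` to 24 (ZT12–24 for
  12:12).
* All intervals are half-open: dark is `[lights_off, lights_on)`,
  hourly bins `[h, h+1)`, days `[start + k·24 h, start + (k+1)·24 h)`.
  This partitions time with no double counting.
* Days are counted from `experiment_start`, not calendar midnight,
  matching continuous-access experiments that start mid-day.
* Logged timestamps are stored at millisecond resolution. R's `%OS3`
  formatter truncates fractional seconds, so the writer biases by half
  a millisecond to round correctly; write→read→write is byte-stable.

## Analysis definitions and numerical choices

* **Bout threshold.** A drinking event qualifies as a bout for analysis
  when it contains at least `min_licks_per_bout` licks (default 20).
  The simulator logs *all* drinking events and the threshold is applied
  at analysis time by `filter_bouts()`, since thresholding is an
  analysis convention, not a property of the hardware.
* **Analysis window.** `filter_bouts()` restricts to
  `[start, start + n_days)`; a bout deferred past the window's end by
  spout contention would otherwise appear in time-keyed tables and not
  in day-keyed ones. Within the window, every aggregation (daily,
  light/dark, hourly-ZT, lick-range) sums exactly the same bouts, so
  totals agree to floating-point roundoff.
* **Dose.** g/kg = volume × ethanol fraction (v/v) × 0.789 g/mL ÷ body
  mass. The ethanol density default is the room-temperature value and
  is configurable. A single body mass per subject is used; per-day mass
  trajectories are out of scope (the registry can be swapped per
  analysis window).
* **Preference** is volume-based: 100 × ethanol mL / total mL. A
  dose-based variant can be computed from `daily_intake()` output.
  0/0 preference is emitted as a flagged-missing row, never as 0.
* **Volume per lick** is the pooled estimate Σvolume/Σlicks per
  subject × fluid, not the mean of per-bout ratios; the pooled form
  weights licks equally and is stable for small bouts.
* **Lick-range bins.** Default edges 20, 45, 70, 95, 120, 145, 170,
  195 with an open top bin: eight ranges of width 25 starting at the
  bout threshold. The edges are configuration, not a claim.
* **Bout frequency** is bouts per day over the whole window, counting
  zero-bout days in the denominator; empty subject × fluid strata are
  flagged `empty` rather than dropped.
* **Lick microstructure.** Interlick intervals are computed within
  bouts only (pairs spanning a bout boundary are excluded); bout
  duration is first-to-last lick; lick frequency is `(n−1)/duration`,
  undefined (flagged) for one-lick bouts; interbout interval is the gap
  from one bout's end to the next bout's start on the same device.
  Because timestamps live on the POSIXct epoch scale, sub-second
  quantities carry ~10⁻⁷ s float granularity; tests use tolerances
  above that floor.
* **Validation.** `validate_session()` checks device exclusivity
  (overlapping bout intervals on one device), registry coverage, field
  sanity, timestamp order, and flags bouts whose duration implies a
  lick rate above ~33 Hz (physiologically impossible; 30 ms minimum
  interlick interval).

## What the generator emulates — and what it does not

Emulated: 2–8 rats sharing 1–2 devices; 12:12 (or any) light cycle with
strong dark-phase drinking; stable per-rat fluid preference; lognormal
bout sizes; ~6.7 Hz gamma lick rhythm; step-quantized pump volumes with
mechanical noise; spout contention with deferral; access restriction
with extinction-probe rows (licks logged, volume zero).

Not emulated: meal-anchored or socially structured drinking, rank
dynamics, spatial behaviour, sensor artefacts (missed or phantom licks,
RFID misreads), evaporation or leakage, per-day body-mass change, and
drift in pump calibration. Passing parameter-recovery tests therefore
demonstrates that the analysis chain is correct and unbiased *given the
log format and the stated conventions* — not that real rats satisfy the
model. Analyses of real logs inherit only the former guarantee.

## Test and acceptance problem sizes

The package's own verification uses study-scale problems chosen to
exercise every code path while staying quick: 4 rats × 9 simulated days
for conservation and recovery properties (100 sessions for exact
volume conservation; 20 seeds per condition for dark-share ratios
r ∈ {1, 3, 10} and choice probabilities p ∈ {0.25, 0.5, 0.8}, asserted
within 3 Monte-Carlo standard errors); 100 randomized 6 h sessions for
round-trip identity; 20 trials at 1.00 mL for the bench dispense
protocol. `scripts/acceptance.R` reruns the full pipeline at the 4 × 9
scale from a single `--seed` and writes the headline quantities as
JSON.

## Known limitations

* The CSV dialects (`datetime,device_id,fluid,rfid,licks,volume_mL,`
  `duration_s`; `datetime,device_id,rfid`) are declared normative for
  this package; a physical device's firmware may order or name columns
  differently, in which case logs need a one-line header rename.
* The occupancy-retry policy (exponential, mean 30 s, 3 retries) is a
  modelling choice; real animals' queueing behaviour is unknown.
* Inferential statistics (ANOVA, post-hoc tests) are deliberately out
  of scope: the package emits tidy tables that slot into standard R
  tooling.
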