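---
title: "Reducing and pooling legacy accelerometer count data with accelpool"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reducing and pooling legacy accelerometer count data with accelpool}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(accelpool)
```

## The problem

Large pooled analyses of children's physical activity combine raw count
files from many studies that used legacy uniaxial Actigraph monitors (7164,
71256, GT1M). The devices integrate acceleration over a fixed *epoch*
(5--60 s) and store one dimensionless count per epoch, saturating at 32767.
Before any epidemiology can happen, every file must pass through the same
reduction pipeline: quality flagging, harmonization to 60-s epochs,
separation of non-wear from sedentary time, conversion of counts to
intensity minutes, valid-day selection, and a join to phenotype data.
`accelpool` implements that pipeline as a tested library with a synthetic
cohort generator, so every stage can be exercised and audited without access
to any restricted study data.

All clock arithmetic uses the device's naive local clock: datetimes are
held in a zone-free container and daylight-saving events are supplied
explicitly per study (§DST below). This keeps multi-country, multi-year
batches auditable; nothing is inferred from a timezone database.

## Wear and non-wear

The monitor is considered not worn wherever a period of **≥ 60 minutes of
consecutive zero counts** occurs, allowing **up to 2 minutes of nonzero
interruptions** inside the period. Three choices the rule's prose leaves
open are fixed here:

* a qualifying period must begin and end on a zero minute, so a lone spike
  can never extend non-wear;
* the interruption magnitude is unbounded by default (any nonzero count can
  be one of the ≤ 2 interruptions); a per-minute count cap is available in
  `detect_nonwear(interruption_cap = )` for sensitivity analyses;
* overlapping qualifying periods are unioned, and interruption minutes
  inside a period are themselves coded non-wear.

`detect_nonwear()` runs in linear time by scanning only the start of each
maximal zero run (any qualifying window is contained in the maximal window
anchored there). Its independent check, `nonwear_oracle()`, enumerates every
candidate window in C++ at quadratic cost; the test suite asserts exact
equality between the two on hundreds of seeded random series. Non-wear
zeros are thereby separated from legitimate sedentary zeros and excluded
from all downstream totals.

Days are local-clock calendar days (midnight to midnight). A day is *valid*
when wear time meets an inclusive criterion (480 minutes satisfy ≥ 8 h);
8, 10 and 12 h are built in and configurable. Partial first/last days are
included by default -- a partial day can still reach 8 h of wear -- with an
exclusion switch in `valid_days()`. Valid-day distributions are tabulated by
sex and age bin (3--5, 6--8, 9--11, 12--14, 15--18 years) with counts capped
at 7, so each row sums to 100% and the cumulative columns satisfy
`ge1 = 100 - d0` and `ge4 = d4 + ... + d7` exactly.

## File-quality flagging

Every file receives exactly one flag with precedence
`CORRUPT > NO_WEAR > TEMPORALLY_SHIFTED > SPURIOUS > OK`; the report keeps
the evidence of every rule that fired, even when outranked. Corrupt means
unparseable (the parser raises a structured error with a byte offset);
no-wear means zero wear minutes after segmentation.

Two automated rules generate evidence:

1. **Overnight wear**: ≥ 10 wear minutes within a single night clock hour
   (02:00--03:00, 03:00--04:00 or 04:00--05:00). Read per single hour
   because "hour 2, 3 and/or 4" enumerates hours; the summed alternative is
   `cleaning_config(overnight_per_hour = FALSE)`. Overnight wear alone is a
   trigger for adjudication, not a defect: it may be legitimate sleep wear,
   a shifted clock, or a sensor fault.
2. **Plateau**: ≥ 3 identical consecutive counts at a value ≥ 10, the
   classic signature of a failing unit; runs at 32767 are additionally
   tagged as saturation.

The original adjudication of overnight wear was visual; a reproducible
pipeline needs deterministic stand-ins, so two detectors automate it:

* `detect_temporal_shift()` fires only when *every* complete day (≥ 2
  required) shows both symptoms of a clock offset: ≥ 30 nonzero minutes in
  the night block (00:00--05:00) and ≥ 180 non-wear minutes in the day
  block (09:00--18:00). The day symptom is measured on the wear mask rather
  than on raw zero runs so that the ≤ 2 interruption minutes the wear rule
  tolerates cannot break a shifted file's daytime zero block. The shift size
  is the circular lag (whole hours) maximizing the correlation between the
  file's mean diurnal profile and a template profile -- by default a
  trapezoid over a 07:00--22:00 waking day with half-hour ramps. The
  template matters: an asymmetric or misaligned template biases the lag
  estimate, so studies with atypical waking days should supply their own via
  `cleaning_config(shift_template = )`. Small offsets that leave the day
  block active (e.g. +3 h against a 07:00--22:00 day) produce no symptom
  and are by design not flagged: the rule detects the described symptom,
  not arbitrary rotations.
* `detect_no_baseline_return()` detects the constant nonzero night floor of
  a sensor that no longer returns to zero: ≥ 3 consecutive night clock
  hours (00:00--06:00) whose minutes are all nonzero, on every complete
  day. This numeric criterion is this package's own; the threshold count of
  hours is configurable.

A file is `SPURIOUS` when plateau evidence exists or when overnight wear is
attributed to a baseline floor; legitimate overnight wear (neither detector
fires) classifies `OK`, and an `OK` report carries no evidence rows.

Duplicate monitors on one participant are resolved before flagging: the
non-corrupt file wins; if both parse, the lexicographically first file
label wins; losers are flagged `DUPLICATE_DROPPED` with the winner's key
recorded.

## Epoch harmonization and DST

`reintegrate()` sums sub-minute epochs into 60-s epochs, drops a trailing
partial block into the provenance log, conserves total counts exactly up to
that tail, and is idempotent at the target epoch.

Recordings spanning a daylight-saving event are normalized so every
complete day has exactly 1440 minutes:

* *spring forward*: the missing hour is imputed as the 30 minutes
  immediately before the event followed by the 30 minutes immediately
  after, inserted at the event -- this ordering preserves temporal
  adjacency at both edges, which the imputation rule's prose does not fix;
* *fall back*: of the 120 recorded minutes mapping onto the doubled local
  hour, only the middle 60 (minutes 30--89 of the doubled span) are kept.
  "Middle hour" admits a second reading (keep the first repetition); the
  middle-60 reading is the default and the literal one.

Events within 30 (spring) or 120 (fall) minutes of a recording boundary are
handled by zero-padding or truncating the affected block, with a warning.
Imputed and collapsed ranges are recorded in the per-file provenance and
excluded from nothing downstream, so all files compare equally.

## Outcome variables

Cutpoint sets map counts per minute to sedentary/light/moderate/vigorous
categories. Intervals are lower-bound inclusive and the values are
configuration, not constants: the built-in registry ships Evenson
(100/2296/4012), Puyau (800/3200/8200) and Mattocks (100/3581/6130)
children's sets, and every summary column is prefixed with the set name so
several sets coexist in one table. MVPA is the union of moderate and
vigorous. Bouts are maximal runs at/above the target intensity with zero
tolerated interruptions by default (`bout_minutes(tolerance = )` exists but
interruption minutes never accrue to a bout, and non-wear always breaks
one); bout minutes are binned as [1, 10) and [10, ∞), a 10-minute bout
falling in the upper bin. Bouts are accounted within calendar days, so a
run crossing midnight contributes to both days' bins. Clock windows are
half-open `[start, end)`, may wrap midnight, and may overlap (a minute can
count in several custom windows); the built-in `hr1..hr24` windows
partition each day exactly.

Per-day summaries satisfy, and the tests assert, the exact identities:
intensity minutes partition wear minutes within every cutpoint set; bout
bins sum to MVPA minutes; hourly windows sum to daily totals; mean counts
per wear minute times wear minutes equals total counts over wear minutes;
and changing cutpoint sets never changes wear minutes. A machine-readable
data dictionary is emitted with every summary export.

## Pooling

Phenotype tables are harmonized per study: a variable enters the pooled
database only if declared by ≥ 3 contributing studies (judged on declared
columns, not non-missing counts); categorical responses pass through
explicit per-study recode maps (an unmapped response is logged and set
missing, never coerced); unit conversions are applied per study. Rows
lacking age or sex are excluded with `MISSING_PHENOTYPE` flags -- those two
variables are the admission ticket.

Participants receive opaque pooled ids from a salted keyed hash:
deterministic given the seed, collision-checked with automatic re-salting,
leak-checked so no source identifier substring survives, and stable across
waves (the wave is not hashed). The pooled table is long format -- one row
per file-day -- because repeated measures and baseline extraction (earliest
wave per id; "baseline" is taken as earliest wave, an assumption) then need
no reshaping. Rows from spurious or shifted files are retained but marked
`excluded_by_default`, mirroring a flag-and-recommend policy rather than
deletion. The attrition table reconciles exactly: every file presented ends
up viable, duplicate-dropped, missing-phenotype, no-wear, corrupt, or
flagged. Builds are byte-identical on identical inputs (stable sort keys,
seeded ids).

## The synthetic cohort generator

`generate_cohort()` emulates the data the pipeline was built for: waking-day
wear (07:00--22:00) with overnight removal, optional daytime removal
episodes (60--150 min), a sedentary/light background with short MVPA bursts
of geometric length, and counts drawn uniformly within the active cutpoint
interval of each minute's true category so that intensity classification
recovers the truth exactly. Deployment length defaults to 7 days and ages
to 6--18 years, the typical school-age deployment; epoch lengths of
5--60 s are supported, with sub-minute files built so reintegration
recovers the minute-level truth exactly.

Three structural guarantees make the generated truth identifiable by the
pipeline's own rules, and the tests rely on them: every 15-minute wear
block contains a nonzero minute (wear can never be absorbed into a non-wear
window); the first and last three minutes of each wear segment are nonzero
(non-wear windows cannot creep across a boundary); and no accidental run of
three identical counts ≥ 10 survives generation (the plateau rule fires
only on injected plateaus). Overnight non-wear episodes may contain 1--2
isolated spike minutes -- exactly the interruptions the wear rule
tolerates.

`inject_artifact()` adds one of the three device faults with presets chosen
to exceed the detection thresholds by construction: a +6 h whole-series
rotation, a 30-minute saturation plateau at 32767, or a night floor of
30--35 counts (jittered so the floor itself does not read as a plateau).
Sub-threshold parameters are allowed but labeled as such.

What the generator does *not* emulate: population-realistic count
distributions (counts are uniform within category intervals), seasonal or
weekday structure, monitor-to-monitor calibration drift, or gradual battery
decay. Passing tests therefore demonstrate the pipeline's rules are
implemented exactly as specified and are mutually consistent -- not that
the flag thresholds are optimal for any particular real cohort.

## Problem sizes and numerical choices

The test suite checks the non-wear rule against the exhaustive oracle on
500 random series of 2000 minutes; artifact recovery on a 200-file cohort
with 20% injected artifacts; conservation identities on 100 files across
epoch lengths 5--30 s; and end-to-end byte-identical reruns on a 10-file
cohort. These sizes give exact, reproducible checks in well under typical
package-check budgets. Ties in the shift-lag correlation are broken toward
the smaller lag (`which.max`); degenerate inputs (all-zero files,
single-day files, zero-wear days) are covered by dedicated tests.
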