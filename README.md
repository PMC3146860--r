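# accelpool

Standardized reduction and pooling of legacy uniaxial accelerometer count
data, for researchers harmonizing physical-activity files across studies.

Legacy Actigraph monitors (7164, 71256, GT1M) store one integer count per
epoch (5–60 s, saturating at 32767) in plain-text `.dat` files. Pooling such
files across cohorts requires one auditable pipeline: quality flagging,
epoch harmonization, wear/non-wear segmentation, intensity and bout
summarization, valid-day selection, and a join to phenotype data.
`accelpool` implements each stage as a tested function and ships a
synthetic-cohort generator with full ground truth, so the whole pipeline is
verifiable without any restricted study data.

The core rules, in the field's standard form:

* **Non-wear**: a period of ≥ 60 min of consecutive zero counts, allowing
  ≤ 2 min of nonzero interruptions, anywhere in the array; windows must
  start and end on zeros, overlapping windows are unioned, and non-wear
  zeros are excluded from all totals (they are not sedentary time).
  A quadratic exhaustive oracle (`nonwear_oracle()`) independently verifies
  the linear-time implementation.
* **Flags** (one per file, precedence `CORRUPT > NO_WEAR >
  TEMPORALLY_SHIFTED > SPURIOUS > OK`): overnight wear of ≥ 10 min within a
  single night hour (02–05 h) triggers adjudication; ≥ 3 identical
  consecutive counts at ≥ 10 (plateau, most often at 32767) and a
  non-returning night floor mark a file spurious; night activity plus
  day-block non-wear on every monitored day marks it temporally shifted,
  with the shift estimated by circular correlation against a diurnal
  template.
* **Outcomes**: per-minute counts map to sedentary/light/moderate/vigorous
  via configurable cutpoint sets (Evenson, Puyau, Mattocks built in;
  lower-bound inclusive); MVPA bout minutes are binned [1, 10) / [10, ∞)
  with zero interruption tolerance; hourly windows `hr1..hr24` and custom
  clock windows `[start, end)` summarize time of day; a day is valid at
  ≥ 8/10/12 h of wear (inclusive).
* **Pooling**: phenotype variables need ≥ 3 contributing studies; rows need
  age and sex at minimum; participants get salted, collision-checked opaque
  ids stable across waves; flagged files are kept but marked
  `excluded_by_default`; the attrition table reconciles every file
  presented.

See `vignettes/accelpool-methods.Rmd` for the full account of the rules,
defaults and design choices.

## Worked example

```r
library(accelpool)

cfg <- sim_config(n_participants = 4, seed = 2027,
                  artifact_rates = c(saturation_plateau = 0.4))
co  <- generate_cohort(cfg)

s <- co$files[[1]]
s
#> <epoch_series> SYNTH_0001_w1 | model GT1M | serial MAT200001
#>   start 2005-04-11 00:00:00, epoch 60 s, 10080 epochs (7.0 days)

rep1 <- classify_file(s)
rep1
#> <flag_report> SYNTH|SYNTH0001|1|MAT200001|SYNTH_0001_w1: SPURIOUS (1 evidence rows)
rep1$evidence
#>   rule_id start_epoch end_epoch                          detail
#> 1 plateau         600       629 saturation plateau (32767) x 30
```

This file received an injected 30-minute saturation plateau starting at
epoch 600 (10:00 of day 1); the flag rule found exactly that run. A clean
file summarizes into per-day outcomes:

```r
cfg2 <- sim_config(n_participants = 4, seed = 2026)
co2  <- generate_cohort(cfg2)
s2   <- co2$files[[1]]
m    <- detect_nonwear(s2)
m
#> <wear_mask> 10080 min: 5991 wear, 4089 nonwear

sm <- summarize_day(s2, m)
sm[1:3, c("date", "wear_minutes", "evenson_sedentary", "evenson_light",
          "evenson_moderate", "evenson_vigorous", "evenson_mvpa",
          "evenson_mvpa_bouts_10plus", "valid_8h")]
#>         date wear_minutes evenson_sedentary evenson_light evenson_moderate
#> 1 2005-04-11          900               464           385               36
#> 2 2005-04-12          753               413           314               18
#> 3 2005-04-13          900               450           386               47
#>   evenson_vigorous evenson_mvpa evenson_mvpa_bouts_10plus valid_8h
#> 1               15           51                        14     TRUE
#> 2                8           26                         0     TRUE
#> 3               17           64                        10     TRUE
```

Each row is one monitored calendar day: 900 wear minutes is the full
07:00–22:00 wear window (day 2 had a removal episode), the four intensity
columns partition wear minutes under the Evenson cutpoints, `evenson_mvpa`
is moderate + vigorous, and `evenson_mvpa_bouts_10plus` is the part of MVPA
accrued in bouts of ten minutes or longer. `valid_days()` then counts valid
days per criterion:

```r
valid_days(day_wear(s2, m))$n_valid
#>  8h 10h 12h
#>   7   7   7
```

A command-line front end over the same functions lives at
`inst/cli/accelpool.R` (`simulate`, `convert`, `reconstitute`, `flag`,
`wear`, `process`, `pool`).

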