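make_wear_day <- function() day_counts(sedentary = 400L, light = 400L,
                                        moderate = 80L, vigorous = 20L)

test_that("duplicate resolution prefers non-corrupt, then first label", {
  a <- minute_series(rep(1L, 60), study_id = "S", participant_id = "p",
                     serial_number = "SN_A", file_label = "fileA")
  b <- minute_series(rep(2L, 60), study_id = "S", participant_id = "p",
                     serial_number = "SN_B", file_label = "fileB")
  # one corrupt -> the non-corrupt wins regardless of label order
  r <- resolve_duplicates(list(a, b), corrupt = c(TRUE, FALSE))
  expect_identical(r$kept$file_label, "fileB")
  expect_identical(r$dropped[[1]]$flag, "DUPLICATE_DROPPED")
  expect_match(r$dropped[[1]]$evidence$detail, "fileB")
  # both fine -> lexicographically first label
  r2 <- resolve_duplicates(list(b, a))
  expect_identical(r2$kept$file_label, "fileA")
  # singleton group: kept unchanged, no drops
  r3 <- resolve_duplicates(list(a))
  expect_identical(r3$kept, a)
  expect_length(r3$dropped, 0L)
  # all corrupt -> first label kept but marked
  r4 <- resolve_duplicates(list(b, a), corrupt = c(TRUE, TRUE))
  expect_identical(r4$kept$file_label, "fileA")
  expect_true(r4$kept_corrupt)
})

test_that("overnight-wear rule fires per single clock hour", {
  base <- integer(1440L)
  # 10 wear minutes 02:05-02:14 (nonzero counts so the mask keeps them wear)
  d <- base
  d[(2 * 60 + 5 + 1):(2 * 60 + 14 + 1)] <- 300L
  d[8 * 60 + 1:600] <- 200L            # daytime wear so file isn't all-zero
  s <- minute_series(d)
  ev <- detect_overnight_wear(s, detect_nonwear(s))
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$rule_id, "overnight_wear")

  # 9 wear minutes in hour 3 -> below threshold
  d9 <- base
  d9[(3 * 60 + 1):(3 * 60 + 9)] <- 300L
  d9[8 * 60 + 1:600] <- 200L
  s9 <- minute_series(d9)
  expect_identical(nrow(detect_overnight_wear(s9, detect_nonwear(s9))), 0L)

  # 5 + 5 wear minutes split across hours 2 and 3 (one contiguous 02:55-03:04
  # run, so the surrounding zeros stay non-wear) -> per-hour reading: no fire
  d55 <- base
  d55[(2 * 60 + 55 + 1):(3 * 60 + 5)] <- 300L
  d55[8 * 60 + 1:600] <- 200L
  s55 <- minute_series(d55)
  expect_identical(nrow(detect_overnight_wear(s55, detect_nonwear(s55))), 0L)
  # ... but the summed alternative does
  cfg_sum <- cleaning_config(overnight_per_hour = FALSE)
  expect_gt(nrow(detect_overnight_wear(s55, detect_nonwear(s55), cfg_sum)), 0L)
})

test_that("plateau detection matches a brute-force scan and tags saturation", {
  s <- minute_series(c(5L, 12L, 12L, 12L, 5L))
  p <- detect_plateaus(s)
  expect_identical(p$start_index, 2L)
  expect_identical(p$length, 3L)
  expect_identical(p$value, 12L)
  expect_false(p$saturation)

  expect_identical(nrow(detect_plateaus(minute_series(rep(9L, 4)))), 0L)

  sat <- minute_series(c(rep_len(c(90L, 110L), 10), rep(32767L, 240),
                         rep_len(c(90L, 110L), 10)),
                       reintegrated = TRUE)
  psat <- detect_plateaus(sat)
  expect_identical(nrow(psat), 1L)
  expect_true(psat$saturation)
  expect_identical(psat$length, 240L)

  set.seed(606)
  for (trial in 1:25) {
    counts <- sample(0:15, sample(50:2000, 1L), replace = TRUE)
    got <- detect_plateaus(minute_series(counts))
    want <- plateau_bruteforce(counts)
    expect_identical(got$start_index, want$start_index)
    expect_identical(got$length, want$length)
    expect_identical(got$value, want$value)
  }
})

test_that("temporal-shift detection recovers the injected lag and rejects clean files", {
  set.seed(707)
  cfg <- sim_config(n_participants = 1, seed = 808)
  co <- generate_cohort(cfg)
  s <- co$files[[1]]
  clean <- detect_temporal_shift(s, detect_nonwear(s))
  expect_false(clean$shifted)
  expect_true(is.na(clean$estimated_shift_hours))

  # shifts large enough to move overnight zeros into the 09:00-18:00 day
  # block (a 3-h shift leaves the day block active and shows no symptom)
  for (h in c(6L, 9L, 12L)) {
    inj <- inject_artifact(s, "temporal_shift", list(shift_hours = h))
    rs <- inj$series
    res <- detect_temporal_shift(rs, detect_nonwear(rs))
    expect_true(res$shifted)
    expect_identical(res$estimated_shift_hours, h)
  }
})

test_that("one anomalous night among five days does not trigger the shift flag", {
  cfg <- sim_config(n_participants = 1, seed = 909, deployment_days = 5L)
  co <- generate_cohort(cfg)
  s <- co$files[[1]]
  # plant activity at 02:00 on day 2 only
  s$counts[1440L + 2L * 60L + 1:60] <- 400L
  res <- detect_temporal_shift(s, detect_nonwear(s))
  expect_false(res$shifted)
})

test_that("shift detection declines on fewer than two complete days", {
  s <- minute_series(rep(c(0L, 5L), 360L))   # a single half day
  res <- detect_temporal_shift(s, detect_nonwear(s))
  expect_false(res$shifted)
  expect_match(res$evidence$detail, "insufficient")
})

test_that("classification follows the flag precedence", {
  # all-zero file -> NO_WEAR
  z <- minute_series(integer(2 * 1440L))
  expect_identical(classify_file(z)$flag, "NO_WEAR")

  # plateau -> SPURIOUS with plateau evidence
  d <- make_wear_day()
  pl <- minute_series(rep(d, 2))
  pl$counts[700:720] <- 32767L
  rep_pl <- classify_file(pl)
  expect_identical(rep_pl$flag, "SPURIOUS")
  expect_true("plateau" %in% rep_pl$evidence$rule_id)

  # clean generated file -> OK with empty evidence
  co <- generate_cohort(sim_config(n_participants = 1, seed = 1010))
  rep_ok <- classify_file(co$files[[1]])
  expect_identical(rep_ok$flag, "OK")
  expect_identical(nrow(rep_ok$evidence), 0L)

  # night floor -> SPURIOUS via non-return-to-baseline
  inj <- inject_artifact(co$files[[1]], "no_baseline_return")
  rep_nbr <- classify_file(inj$series)
  expect_identical(rep_nbr$flag, "SPURIOUS")
  expect_true("no_baseline_return" %in% rep_nbr$evidence$rule_id)

  # shift outranks spurious evidence
  inj2 <- inject_artifact(co$files[[1]], "temporal_shift")
  sh <- inj2$series
  sh$counts[700:704] <- 32767L   # add a plateau on top
  rep_sh <- classify_file(sh)
  expect_identical(rep_sh$flag, "TEMPORALLY_SHIFTED")
  expect_true("plateau" %in% rep_sh$evidence$rule_id)
})

test_that("classification is a pure function of its inputs", {
  co <- generate_cohort(sim_config(n_participants = 1, seed = 1111))
  s <- co$files[[1]]
  m <- detect_nonwear(s)
  expect_identical(classify_file(s, m), classify_file(s, m))
})

test_that("legitimate overnight wear is not flagged", {
  cfg <- sim_config(n_participants = 1, seed = 1212, overnight_wear_prob = 1)
  co <- generate_cohort(cfg)
  s <- co$files[[1]]
  m <- detect_nonwear(s)
  # the overnight-wear trigger fires ...
  expect_gt(nrow(detect_overnight_wear(s, m)), 0L)
  # ... but adjudication finds neither a shift nor a floor: file is OK
  expect_identical(classify_file(s, m)$flag, "OK")
})
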