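demo_cuts <- cutpoint_set("demo", 100, 2000, 4000)

test_that("intensity classification is lower-bound inclusive and excludes non-wear", {
  counts <- c(0L, 99L, 100L, 1999L, 2000L, 3999L, 4000L, 0L)
  s <- minute_series(counts)
  mask <- wear_mask(c(rep(TRUE, 7), FALSE))
  lab <- classify_intensity(s, mask, demo_cuts)
  expect_identical(as.character(lab),
                   c("sedentary", "sedentary", "light", "light", "moderate",
                     "moderate", "vigorous", "nonwear"))
  # a non-wear zero is never sedentary time
  expect_identical(sum(lab == "sedentary"), 2L)
})

test_that("invalid cutpoint sets are rejected", {
  expect_error(cutpoint_set("bad", 100, 100, 4000), "strictly increasing")
  expect_error(cutpoint_registry("nope"), "unknown cutpoint")
})

test_that("bout minutes bin full run lengths with zero tolerance", {
  mk <- function(runs, gap = "sedentary") {
    lab <- unlist(lapply(seq_along(runs), function(i) {
      c(rep("moderate", runs[i]), rep(gap, 2))
    }))
    factor(lab, levels = c("sedentary", "light", "moderate", "vigorous",
                           "nonwear"))
  }
  b <- bout_minutes(mk(c(5, 12, 3)))
  expect_equal(unname(b["1-9min"]), 8)
  expect_equal(unname(b["10+min"]), 12)
  # a 10-min bout belongs to the upper bin (boundary inclusive)
  b10 <- bout_minutes(mk(10))
  expect_equal(unname(b10["10+min"]), 10)
  expect_equal(unname(b10["1-9min"]), 0)
  # a run split by one nonwear minute yields two short bouts
  lab <- factor(c(rep("moderate", 6), "nonwear", rep("moderate", 6)),
                levels = levels(mk(1)))
  bsplit <- bout_minutes(lab)
  expect_equal(unname(bsplit["1-9min"]), 12)
  expect_equal(unname(bsplit["10+min"]), 0)
  # with tolerance 1, a 1-min sedentary interruption is bridged (but not counted)
  lab2 <- factor(c(rep("moderate", 6), "sedentary", rep("moderate", 6)),
                 levels = levels(mk(1)))
  btol <- bout_minutes(lab2, tolerance = 1L)
  expect_equal(unname(btol["10+min"]), 12)
  # nonwear is never bridged
  btol_nw <- bout_minutes(lab, tolerance = 1L)
  expect_equal(unname(btol_nw["1-9min"]), 12)
})

test_that("bout bins partition total MVPA minutes on random labels", {
  set.seed(11)
  lv <- c("sedentary", "light", "moderate", "vigorous", "nonwear")
  for (trial in 1:20) {
    lab <- factor(sample(lv, 500, replace = TRUE, prob = c(.4, .3, .15, .05, .1)),
                  levels = lv)
    b <- bout_minutes(lab)
    expect_equal(sum(b), sum(lab %in% c("moderate", "vigorous")))
  }
})

test_that("hourly windows partition the day; custom windows follow [start, end)", {
  set.seed(12)
  counts <- random_minute_counts(2 * 1440L, p_zero = 0.4)
  s <- minute_series(counts)
  mask <- detect_nonwear(s)
  lab <- classify_intensity(s, mask, demo_cuts)
  ws <- window_summaries(s, mask, lab)
  per_day <- day_wear(s, mask)
  agg <- tapply(ws$wear_minutes, ws$date, sum)
  expect_identical(as.integer(agg), per_day$wear_minutes)
  for (cat in c("sedentary", "light", "moderate", "vigorous")) {
    expect_identical(as.integer(tapply(ws[[cat]], ws$date, sum)),
                     as.integer(tapply(lab == cat,
                                       as.Date(epoch_timestamps(s), tz = "UTC"),
                                       sum)))
  }
  # minute at 08:59 belongs to hr9 = [08:00, 09:00)
  hr9 <- ws[ws$window == "hr9" & ws$date == as.Date("2005-04-11"), ]
  expect_identical(hr9$monitored_minutes, 60L)
  # custom window captures 07:30-08:29
  cw <- window_summaries(s, mask, lab, time_window("commute", "07:30", "08:30"))
  expect_identical(cw$monitored_minutes[1], 60L)
  # midnight-wrapping window
  wrap <- window_summaries(s, mask, lab, time_window("night", "23:00", "01:00"))
  expect_identical(sum(wrap$monitored_minutes), 240L)
})

test_that("day summaries satisfy the partition identities", {
  co <- generate_cohort(sim_config(n_participants = 3, seed = 1313,
                                   removal_prob = 0.5))
  reg <- cutpoint_registry()
  for (id in names(co$files)) {
    s <- co$files[[id]]
    m <- detect_nonwear(s)
    sm <- summarize_day(s, m, registry = reg)
    for (cs in reg) {
      cats <- paste0(cs$name, "_", cs$categories)
      expect_identical(Reduce(`+`, sm[cats]), sm$wear_minutes)
      expect_equal(sm[[paste0(cs$name, "_mvpa_bouts_1_9")]] +
                     sm[[paste0(cs$name, "_mvpa_bouts_10plus")]],
                   as.numeric(sm[[paste0(cs$name, "_mvpa")]]))
    }
    # exact integer identity: mean counts/wear-min times wear minutes
    ok <- sm$wear_minutes > 0
    expect_equal(sm$counts_per_wear_minute[ok] * sm$wear_minutes[ok],
                 as.numeric(sm$total_counts[ok]))
  }
})

test_that("changing the cutpoint set never changes wear minutes", {
  co <- generate_cohort(sim_config(n_participants = 1, seed = 1414))
  s <- co$files[[1]]
  m <- detect_nonwear(s)
  a <- summarize_day(s, m, registry = cutpoint_registry("evenson"))
  b <- summarize_day(s, m, registry = cutpoint_registry("puyau"))
  expect_identical(a$wear_minutes, b$wear_minutes)
  expect_identical(a$monitored_minutes, b$monitored_minutes)
})

test_that("summaries reproduce the generator's ground truth with the true mask", {
  cfg <- sim_config(n_participants = 2, seed = 1515)
  co <- generate_cohort(cfg)
  for (id in names(co$files)) {
    s <- co$files[[id]]
    tr <- co$truth[[id]]
    sm <- summarize_day(s, tr$wear, registry = list(cfg$cutpoints))
    nm <- cfg$cutpoints$name
    for (cat in c("sedentary", "light", "moderate", "vigorous")) {
      expect_identical(sm[[paste0(nm, "_", cat)]], tr$day_minutes[[cat]])
    }
    expect_identical(sm$wear_minutes, tr$day_minutes$wear_minutes)
  }
})

test_that("degenerate days summarize cleanly", {
  # all-wear sedentary day
  s <- minute_series(rep(50L, 1440L))
  sm <- summarize_day(s, wear_mask(rep(TRUE, 1440L)),
                      registry = list(demo_cuts))
  expect_identical(sm$demo_sedentary, 1440L)
  expect_identical(sm$demo_mvpa, 0L)
  expect_equal(sm$demo_mvpa_bouts_10plus, 0)
  # zero-wear day
  z <- minute_series(integer(1440L))
  smz <- summarize_day(z, registry = list(demo_cuts))
  expect_identical(smz$wear_minutes, 0L)
  expect_identical(smz$demo_sedentary, 0L)
  expect_false(smz$valid_8h)
  expect_true(is.na(smz$counts_per_wear_minute))
})

test_that("the data dictionary describes every emitted column", {
  co <- generate_cohort(sim_config(n_participants = 1, seed = 1616))
  sm <- summarize_day(co$files[[1]])
  dd <- data_dictionary(sm)
  expect_setequal(dd$column, names(sm))
  expect_true(all(nzchar(dd$description[dd$column %in%
                                          c("wear_minutes", "evenson_mvpa")])))
})
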