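phen_tables <- function() {
  list(
    A = data.frame(participant_id = c("a1", "a2"), age = c(10, 11),
                   sex = c("M", "F"), height = c(1.40, 1.45),
                   tv_hours = c("lots", "none"), stringsAsFactors = FALSE),
    B = data.frame(participant_id = c("b1", "b2"), age = c(12, NA),
                   sex = c("male", "female"), height = c(150, 152),
                   stringsAsFactors = FALSE),
    C = data.frame(participant_id = "c1", age = 9, sex = "female",
                   height = 138, stringsAsFactors = FALSE),
    D = data.frame(participant_id = "d1", age = 14, sex = "",
                   tv_hours = "2", stringsAsFactors = FALSE))
}

test_that("variables present in fewer than min_studies studies are dropped", {
  maps <- list(recode_map("height", convert = list(A = "m_to_cm")),
               recode_map("sex", recode = list(
                 A = c(M = "male", F = "female"))))
  h <- harmonize_phenotypes(phen_tables(), maps, min_studies = 3L)
  expect_true("height" %in% names(h$participants))     # in A, B, C
  expect_false("tv_hours" %in% names(h$participants))  # only in A, D
  expect_identical(h$dropped_variables, "tv_hours")
})

test_that("unit conversions and category recodes are applied per study", {
  maps <- list(recode_map("height", convert = list(A = "m_to_cm")))
  h <- harmonize_phenotypes(phen_tables(), maps, min_studies = 3L)
  pa <- h$participants[h$participants$study_id == "A", ]
  expect_equal(pa$height, c(140, 145))                 # metres -> cm
  pb <- h$participants[h$participants$study_id == "B", ]
  expect_equal(pb$height, 150)                         # untouched
})

test_that("rows lacking age or sex are excluded with MISSING_PHENOTYPE flags", {
  h <- harmonize_phenotypes(phen_tables(), min_studies = 3L)
  expect_identical(nrow(h$participants), 4L)           # b2 (no age), d1 (no sex) gone
  flags <- vapply(h$excluded, function(r) r$flag, "")
  expect_identical(flags, rep("MISSING_PHENOTYPE", 2L))
})

test_that("unmapped categories are logged and set missing, never coerced", {
  tabs <- phen_tables()[c("A", "B", "C")]
  tabs$A$diet <- c("fruit", "mystery")
  tabs$B$diet <- "veg"
  tabs$C$diet <- "fruit"
  maps <- list(recode_map("diet", recode = list(
    A = c(fruit = "healthy"), B = c(veg = "healthy"), C = c(fruit = "healthy"))))
  h <- harmonize_phenotypes(tabs, maps, min_studies = 3L)
  expect_identical(nrow(h$recode_errors), 1L)
  expect_identical(h$recode_errors$value, "mystery")
  pa <- h$participants[h$participants$study_id == "A", ]
  expect_identical(pa$diet, c("healthy", NA))
})

test_that("pooled ids are deterministic, distinct, stable across waves, non-identifying", {
  rec <- data.frame(study_id = c("S1", "S1", "S2", "S1"),
                    participant_id = c("child007", "child008", "child007",
                                       "child007"),
                    wave = c(1L, 1L, 1L, 2L), stringsAsFactors = FALSE)
  a <- assign_ids(rec, seed = 5L)
  b <- assign_ids(rec, seed = 5L)
  expect_identical(a, b)
  # same participant, different wave -> same id
  expect_identical(a$pooled_id[1], a$pooled_id[4])
  # same source id in different studies -> different pooled id
  expect_false(a$pooled_id[1] == a$pooled_id[3])
  # no source substring leaks into the id
  expect_false(any(mapply(grepl, rec$participant_id, a$pooled_id, fixed = TRUE)))
  # a different seed permutes ids
  expect_false(identical(assign_ids(rec, seed = 6L)$pooled_id, a$pooled_id))
})

build_toy_db <- function() {
  phen <- data.frame(study_id = "S", participant_id = c("p1", "p2", "p3"),
                     wave = 1L, age = c(8, 10, 12),
                     sex = c("male", "female", "male"),
                     stringsAsFactors = FALSE)
  participants <- assign_ids(rbind(phen, transform(phen, wave = 2L)), seed = 3L)
  mk <- function(pid, wave, label, flag) {
    s <- minute_series(day_counts(sedentary = 600L, light = 200L,
                                  moderate = 30L), study_id = "S",
                       participant_id = pid, wave = as.character(wave),
                       serial_number = "SN", file_label = label)
    list(summary = summarize_day(s), report = flag_report(file_key(s), flag))
  }
  specs <- list(list("p1", 1, "f1", "OK"), list("p2", 1, "f2", "OK"),
                list("p3", 1, "f3", "SPURIOUS"), list("p1", 2, "f4", "OK"),
                list("p2", 2, "f5", "TEMPORALLY_SHIFTED"),
                list("p3", 2, "f6", "OK"))
  parts <- lapply(specs, function(x) mk(x[[1]], x[[2]], x[[3]], x[[4]]))
  list(summaries = do.call(rbind, lapply(parts, `[[`, "summary")),
       reports = lapply(parts, `[[`, "report"),
       participants = participants)
}

test_that("the pooled database keeps flagged rows marked and baseline views distinct", {
  toy <- build_toy_db()
  db <- build_database(toy$summaries, toy$reports, toy$participants)
  expect_identical(nrow(db$data), 6L)                  # 3 participants x 2 waves
  expect_identical(sum(db$data$excluded_by_default), 2L)
  expect_true(all(c("age", "sex") %in% names(db$data)))
  expect_false(anyNA(db$data$age))
  bl <- db$baseline()
  expect_identical(nrow(bl), 3L)
  expect_identical(sort(unique(bl$wave)), "1")
  # one row-group per pooled id in the baseline view
  expect_identical(anyDuplicated(bl$pooled_id), 0L)
})

test_that("orphan summaries are a hard error", {
  toy <- build_toy_db()
  expect_error(build_database(toy$summaries, toy$reports[-1],
                              toy$participants), "without a flag report")
  orphan_phen <- toy$participants[-(1:2), ]            # drop p1 rows entirely
  orphan_phen <- orphan_phen[orphan_phen$participant_id != "p1", ]
  expect_error(build_database(toy$summaries, toy$reports, orphan_phen),
               "matching participant")
})

test_that("attrition accounting reconciles every file presented", {
  cfg <- sim_config(n_participants = 12, seed = 1717,
                    artifact_rates = c(temporal_shift = 0.2,
                                       saturation_plateau = 0.1,
                                       no_baseline_return = 0.1))
  co <- generate_cohort(cfg)
  reports <- lapply(names(co$files), function(id) {
    classify_file(co$files[[id]])
  })
  # add upstream flags: one duplicate drop, one missing-phenotype
  reports <- c(reports,
               list(flag_report("S|x|1|SN|dup", "DUPLICATE_DROPPED",
                                accelpool:::new_evidence("duplicate", 1L, 1L, "x")),
                    flag_report("S|y|1|SN|nophen", "MISSING_PHENOTYPE",
                                accelpool:::new_evidence("missing_phenotype",
                                                         NA, NA, "no age"))))
  tab <- table(vapply(reports, function(r) r$flag, ""))
  expect_identical(sum(tab), length(reports))          # every file accounted once
  viable <- sum(tab[c("OK")])
  flagged <- sum(tab[names(tab) %in% c("SPURIOUS", "TEMPORALLY_SHIFTED")])
  other <- sum(tab[names(tab) %in% c("DUPLICATE_DROPPED", "MISSING_PHENOTYPE",
                                     "NO_WEAR", "CORRUPT")])
  expect_identical(viable + flagged + other, length(reports))
})

test_that("rebuilding on identical inputs is byte-identical", {
  co <- generate_cohort(sim_config(n_participants = 4, seed = 1818))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  run_pipeline_to_dir(co, d1, pool_seed = 9L)
  run_pipeline_to_dir(co, d2, pool_seed = 9L)
  for (f in c("flags.tsv", "pooled.tsv", "attrition.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})
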