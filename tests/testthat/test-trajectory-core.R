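test_that("codes truncate to the three-character ICD category", {
  expect_equal(truncate_code("C25.1"), "C25")
  expect_equal(truncate_code("C25"), "C25")
  expect_equal(truncate_code("K85.90"), "K85")
  expect_equal(truncate_code(c("a01.5", "B99 1")), c("A01", "B99"))
  expect_error(truncate_code("C2"), "fewer than 3")
  expect_error(truncate_code(c("C25", "")), "empty")
})

test_that("calendar month arithmetic clamps the day of month", {
  expect_equal(add_months(d_("2001-01-31"), 1), d_("2001-02-28"))
  expect_equal(add_months(d_("2000-01-31"), 1), d_("2000-02-29")) # leap year
  expect_equal(add_months(d_("2000-03-15"), -24), d_("1998-03-15"))
  expect_equal(add_months(d_("2010-11-30"), 3), d_("2011-02-28"))
})

test_that("horizon labels are a step function at the cancer date", {
  # control: all zeros, all informative
  lab <- label_horizons(d_("2010-01-01"), as.Date(NA))
  expect_equal(lab$y, rep(0L, 5))
  expect_equal(lab$mask, rep(1L, 5))

  # cancer ~8 months after assessment: step between the 6 and 12 horizon
  lab <- label_horizons(d_("2010-01-15"), d_("2010-09-10"))
  expect_equal(lab$y, c(0L, 0L, 1L, 1L, 1L))
  expect_equal(lab$mask, c(1L, 1L, 1L, 0L, 0L)) # first positive kept

  # cancer ~48 months out: only the 60-month horizon covers it
  lab <- label_horizons(d_("2010-01-15"), d_("2014-01-20"))
  expect_equal(lab$y, c(0L, 0L, 0L, 0L, 1L))
  expect_equal(lab$mask, rep(1L, 5))

  # unmasked variant keeps all five horizons
  lab <- label_horizons(d_("2010-01-15"), d_("2010-09-10"), mask_mode = "all")
  expect_equal(lab$mask, rep(1L, 5))

  expect_error(label_horizons(d_("2010-01-01"), d_("2009-12-31")),
               "must precede")
})

test_that("eligibility filter drops short and unassessable patients", {
  co <- eligibility_filter(toy_cohort())
  expect_setequal(co$patients$patient_id, c("A", "B", "C"))
  tally <- attr(co, "tally")
  expect_equal(unname(tally["too_few_events"]), 1) # D
  expect_equal(unname(tally["no_admissible_assessment"]), 1) # E
  expect_equal(unname(tally["kept"]), 3)
})

test_that("partial trajectory enumeration matches hand counts", {
  co <- eligibility_filter(toy_cohort())
  traj <- enumerate_partial_trajectories(co)
  expect_equal(sum(traj$patient_id == "A"), 3) # endpoints 5, 6, 7
  expect_equal(sum(traj$patient_id == "B"), 1)
  expect_equal(sum(traj$patient_id == "C"), 2) # endpoints 5, 6 (pre-cancer)
  expect_true(all(traj[traj$patient_id == "C"]$is_case))
  expect_true(all(traj[traj$patient_id == "C"]$assessment_date <
                    d_("2010-06-15")))
  # ages derive from birth date
  a <- traj[traj$patient_id == "A"][1]
  expect_equal(a$age_at_assessment,
               as.numeric(a$assessment_date - d_("1950-01-01")) / 365.25)
})

test_that("a patient with n admissible events yields max(0, n - 4) trajectories", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(1:15, 1)
    dates <- sort(d_("1990-01-01") + sample(0:5000, n, replace = TRUE))
    patients <- data.frame(patient_id = "X", birth_date = d_("1950-01-01"),
                           sex = NA, end_of_data = d_("2018-01-01"),
                           cancer_date = d_(NA))
    events <- data.frame(patient_id = "X", date = dates,
                         code = sprintf("Q%02d", seq_len(n) %% 100),
                         system = "icd10")
    traj <- enumerate_partial_trajectories(as_cohort(patients, events))
    # all events are > 24 months before end_of_data, so all are admissible
    expect_equal(nrow(traj), max(0, n - 4))
  }
})

test_that("labels are monotone over horizons for every generated trajectory", {
  d <- small_gen_data()
  Y <- as.matrix(d$trajectories[, paste0("y", c(3, 6, 12, 36, 60)),
                                with = FALSE])
  expect_true(all(t(apply(Y, 1, diff)) >= 0))
  # trajectory-level label prevalence grows with the horizon
  expect_true(all(diff(colMeans(Y)) >= 0))
})

test_that("exclusion windows remove only near-diagnosis case events and nest", {
  # cancer patient with events 14, 8 and 2 months before diagnosis
  cd <- d_("2012-06-15")
  patients <- data.frame(patient_id = c("P", "Q"),
                         birth_date = d_("1950-01-01"), sex = NA,
                         end_of_data = d_("2014-12-31"),
                         cancer_date = c(cd, d_(NA)))
  events <- data.frame(
    patient_id = c("P", "P", "P", "Q", "Q"),
    date = c(add_months(cd, -14), add_months(cd, -8), add_months(cd, -2),
             d_("2010-01-01"), d_("2010-06-01")),
    code = c("K10", "K11", "K12", "K13", "K14"), system = "icd10")
  co <- as_cohort(patients, events)

  ex0 <- apply_exclusion_window(co, 0)
  expect_identical(ex0$events, co$events)
  ex3 <- apply_exclusion_window(co, 3)
  expect_setequal(ex3$events[patient_id == "P"]$code, c("K10", "K11"))
  # controls never change
  expect_equal(nrow(ex3$events[patient_id == "Q"]), 2)

  # nesting: event sets shrink as the window grows
  prev <- co$events
  for (m in c(3, 6, 12)) {
    cur <- apply_exclusion_window(co, m)$events
    expect_true(all(paste(cur$patient_id, cur$date, cur$code) %in%
                      paste(prev$patient_id, prev$date, prev$code)))
    prev <- cur
  }
})

test_that("patient-level splits partition patients at the requested ratios", {
  ids <- sprintf("p%02d", 1:10)
  sp <- split_by_patient(ids, seed = 3)
  expect_equal(as.integer(table(sp$assignment)[c("train", "dev", "test")]),
               c(8L, 1L, 1L))
  expect_setequal(names(sp$assignment), ids)
  # determinism
  expect_identical(sp$assignment, split_by_patient(ids, seed = 3)$assignment)
  expect_false(identical(sp$assignment,
                         split_by_patient(ids, seed = 4)$assignment))
  expect_error(split_by_patient(c("a", "b"), seed = 1), "at least 3")

  # all of a patient's trajectories inherit one split label
  d <- small_gen_data()
  per_patient <- tapply(d$trajectories$split, d$trajectories$patient_id,
                        function(x) length(unique(x)))
  expect_true(all(per_patient == 1))
})

test_that("balanced batches hold exactly ceil/floor class counts", {
  is_pos <- c(rep(TRUE, 3), rep(FALSE, 1000))
  batches <- balanced_batch_sampler(is_pos, 8, seed = 5)
  expect_equal(length(batches), ceiling(1000 / 4))
  for (b in batches) {
    expect_length(b, 8)
    expect_equal(sum(is_pos[b]), 4) # minority resampled with replacement
  }
  # batch_size 2: one of each
  b2 <- balanced_batch_sampler(is_pos, 2, seed = 5, n_batches = 10)
  expect_true(all(vapply(b2, function(b) sum(is_pos[b]), numeric(1)) == 1))
  # determinism
  expect_identical(batches, balanced_batch_sampler(is_pos, 8, seed = 5))
  expect_error(balanced_batch_sampler(rep(TRUE, 5), 4, 1), "negative")
  expect_error(balanced_batch_sampler(rep(FALSE, 5), 4, 1), "positive")
})

test_that("cross-system mapping rewrites, prefixes and tallies codes", {
  events <- data.table::data.table(
    patient_id = "v", date = d_("2001-01-01") + 0:2,
    code = c("157", "410", "157"), system = "icd9")
  map <- data.frame(from = "157", to = "C25")
  out <- map_code_system(events, map, target_prefix = "D")
  expect_equal(out$code, c("DC25", "DC25"))
  expect_equal(unique(out$system), "icd10")
  expect_equal(unname(attr(out, "unmapped")["410"]), 1)
  # keep-mode retains unmapped rows untouched
  kept <- map_code_system(events, map, unmapped = "keep")
  expect_equal(nrow(kept), 3)
  expect_equal(kept$code[2], "410")
  # empty inputs
  expect_equal(nrow(map_code_system(events[0], map)), 0)
  expect_error(map_code_system(events, data.frame(from = character(0),
                                                  to = character(0))),
               "empty mapping")
})

test_that("event and patient files round-trip through disk", {
  co <- toy_cohort()
  ef <- tempfile(fileext = ".tsv")
  pf <- tempfile(fileext = ".tsv")
  write_event_file(co$events, ef)
  write_patient_file(co$patients, pf)
  back <- read_cohort(ef, pf)
  expect_equal(as.data.frame(back$events), as.data.frame(co$events))
  expect_equal(as.data.frame(back$patients[order(patient_id)]),
               as.data.frame(co$patients[order(patient_id)]))

  # empty tables round-trip as header-only files
  write_event_file(co$events[0], ef)
  expect_equal(nrow(read_event_file(ef)), 0)

  # malformed dates are reported with their line number
  writeLines(c("patient_id\tdate\tcode\tsystem",
               "p1\t2001-01-01\tA10\ticd10",
               "p1\tnot-a-date\tA11\ticd10"), ef)
  expect_error(read_event_file(ef), "line 3")
})

test_that("vocabularies keep code systems apart and index contiguously", {
  events <- data.frame(code = c("C25", "C25", "A10"),
                       system = c("icd10", "icd8", "icd10"))
  v <- build_vocabulary(events)
  expect_length(v$tokens, 3) # C25 appears once per system
  expect_equal(sort(unname(v$index)), 1:3)
  expect_equal(v$pad_index, 4L)
  expect_error(trajrisk:::vocab_lookup(v, "icd10", "Z99"), "absent")
})
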