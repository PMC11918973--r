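test_that("days in other wards or specialized beds are masked to 'other'", {
  rec <- make_case_records("p1", "2017-05-01", list(0, "other", 2, 3))
  case <- process_case(rec, target_ward = "test")
  expect_identical(case$states[1:3], c("0", "other", "2"))
  # a specialized bed inside the target ward is masked the same way
  rec2 <- make_case_records("p1", "2017-05-01", list(0, "sp", 2, 2))
  expect_identical(process_case(rec2, "test")$states[2], "other")
})

test_that("days after the discharge entry date become 'discharged'", {
  rec <- make_case_records("p2", "2017-05-01", list(1, 1, 0, 0, "end"))
  case <- process_case(rec, target_ward = "test")
  expect_identical(case$states[1:4], c("1", "1", "0", "0"))
  expect_true(all(case$states[5:18] == "discharged"))
})

test_that("a full in-ward stay passes through unchanged", {
  scores <- rep(list(2), 18)
  case <- process_case(make_case_records("p3", "2017-05-01", scores), "test")
  expect_identical(case$states, rep("2", 18))
  expect_identical(case$target_days, 18L)
})

test_that("processing is deterministic and repeatable", {
  rec <- make_case_records("p4", "2017-06-01", list(0, "other", "miss", 4, "end"))
  expect_identical(process_case(rec, "test"), process_case(rec, "test"))
})

test_that("invalid and ambiguous records are rejected", {
  bad <- make_case_records("p5", "2017-05-01", list(13))
  bad$score <- 13L
  expect_error(process_case(bad, "test"), "outside 0..12")
  dup <- make_case_records("p6", "2017-05-01", list(1, 2))
  dup$date[2] <- dup$date[1]
  expect_error(process_case(dup, "test"), "conflicting duplicate")
})

test_that("eligibility rules exclude and log the constructed violations", {
  # 10 cases; case 7 has a missing in-ward score, case 9 is admitted after
  # the window closes
  recs <- list()
  for (k in 1:10) {
    plan <- rep(list((k - 1) %% 5), 18)
    if (k == 7) plan[[7]] <- "miss"
    adm <- if (k == 9) "2018-03-20" else "2017-05-01"
    recs[[k]] <- make_case_records(sprintf("p%02d", k), adm, plan)
  }
  cases <- process_records(do.call(rbind, recs), target_ward = "test")
  res <- filter_eligible(cases, fiscal_window(2017), ward = "test",
                         fiscal_year = "2017")
  expect_identical(n_eligible(res$cohort), 8L)
  expect_identical(nrow(res$exclusions), 2L)
  expect_setequal(res$exclusions$reason, c("missing score", "outside window"))
  # accounting: every case lands in the cohort or the log
  expect_identical(length(cases), n_eligible(res$cohort) + nrow(res$exclusions))
  # eligible trajectories are complete
  expect_false(anyNA(res$cohort$states))
})

test_that("a case that never occupies a target-ward general bed is excluded", {
  rec <- make_case_records("p1", "2017-05-01",
                           c(rep(list("other"), 17), list("sp")))
  cases <- process_records(rec, target_ward = "test")
  res <- filter_eligible(cases, fiscal_window(2017))
  expect_identical(n_eligible(res$cohort), 0L)
  expect_identical(res$exclusions$reason, "no target ward day")
})

test_that("exclusion reasons are exhaustive over random generated cohorts", {
  arch <- make_archetype("neurosurgery")
  rec <- generate_cohort(arch, 300, seed = 13, missing_rate = 0.02)
  cases <- process_records(rec, target_ward = "neurosurgery")
  res <- filter_eligible(cases, fiscal_window(2017))
  expect_identical(length(cases), n_eligible(res$cohort) + nrow(res$exclusions))
  expect_true(all(res$exclusions$reason %in%
                  c("outside window", "no target ward day", "missing score")))
})

test_that("cohort summaries report occupancy and quartiles", {
  coh <- cohort_of(traj("0"), traj("1"), traj("4"))
  s <- summarize_cohort(coh, days = 1)
  expect_identical(s$n_inpatient, 3L)
  expect_identical(s$pct_inpatient, 100.0)
  expect_identical(s$score_median, 1)
  expect_identical(s$score_q1, 0.5)
  expect_identical(s$score_q3, 2.5)
  expect_error(summarize_cohort(coh, days = 19), "within")
})

test_that("summaries count 'other' as inpatient but not 'discharged'", {
  coh <- cohort_of(
    traj("3"),
    traj("other"),
    traj("5", "5", "discharged")
  )
  s <- summarize_cohort(coh, days = 3)
  expect_identical(s$n_inpatient, 2L)
  expect_identical(s$pct_inpatient, percent_round(2 / 3))
  expect_identical(s$score_median, 3)  # only the score-state case counts
})

test_that("records and cohorts round-trip through CSV", {
  arch <- make_archetype("cardiology")
  rec <- generate_cohort(arch, 30, seed = 8)
  path <- withr::local_tempfile(fileext = ".csv")
  write_records(rec, path)
  expect_identical(read_records(path), rec)

  cases <- process_records(rec, target_ward = "cardiology")
  coh <- filter_eligible(cases, fiscal_window(2017), ward = "cardiology",
                         fiscal_year = "2017")$cohort
  cpath <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, cpath)
  back <- read_cohort(cpath)
  expect_identical(back$states, coh$states)
  expect_identical(back$ward, coh$ward)
})

test_that("ingest reproduces the generating chain when nothing is missing", {
  arch <- make_archetype("orthopaedic")
  set.seed(21)
  S <- sample_trajectories(arch, 60, seed = 21)
  rec <- generate_cohort(arch, 60, seed = 21, missing_rate = 0)
  cases <- process_records(rec, target_ward = "orthopaedic")
  res <- filter_eligible(cases, fiscal_window(2017))
  # every generated case is eligible and identical to its chain states
  expect_identical(n_eligible(res$cohort), 60L)
  key <- order(as.integer(sub("/.*", "", sub("P", "", rownames(res$cohort$states)))))
  expect_identical(unname(res$cohort$states[key, ]), unname(S))
})
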