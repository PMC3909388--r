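cfg <- generator_config()
crit <- criteria_from_config(cfg)

demo <- function(id, dob, sex) {
  tibble::tibble(patient_id = id, dob = as.Date(dob), sex = sex)
}

test_that("automated matching filters on sex and dob tolerance, keeping order", {
  case <- list(patient_id = "c", dob = as.Date("2000-06-15"), sex = "F")
  cands <- demo(c("k1", "k2", "k3", "k4"),
                c("2001-06-16", "2001-06-15", "2000-06-15", "1999-06-14"),
                c("F", "F", "M", "F"))
  got <- automated_match_pool(case, cands, match_spec())
  # k1 is 366 days away (in); k4 is 367 days away across a leap February
  # (out); k3 is the opposite sex despite an equal dob (out)
  expect_identical(got, c("k1", "k2"))
  relaxed <- automated_match_pool(case, cands,
                                  match_spec(sex_exact = FALSE,
                                             dob_tolerance_days = 400))
  expect_identical(relaxed, c("k1", "k2", "k3", "k4"))
  expect_identical(automated_match_pool(case, cands[0, ]), character(0))
})

test_that("automated matching equals a brute-force filter oracle", {
  set.seed(19)
  for (i in 1:200) {
    case <- list(patient_id = "c",
                 dob = as.Date("2000-01-01") + sample.int(3000, 1),
                 sex = sample(c("M", "F"), 1))
    m <- sample.int(12, 1)
    cands <- demo(paste0("k", seq_len(m)),
                  case$dob + sample(-500:500, m, replace = TRUE),
                  sample(c("M", "F"), m, replace = TRUE))
    expect_identical(automated_match_pool(case, cands, match_spec()),
                     pool_oracle(case, cands))
  }
})

test_that("sequential review stops at the ratio and accounts for reviews", {
  case <- realize_case_disposition("INCLUDED", cfg, 1)$records
  set.seed(4)
  all_ok <- generate_control_stream(case, cfg, intended = rep("ELIGIBLE", 6))
  r <- sequential_review(case, all_ok$records, crit, match_spec(),
                         shuffle = FALSE)
  expect_length(r$control_ids, 2L)
  expect_equal(r$n_reviewed_ineligible, 0L)
  expect_false(r$exhausted)
  expect_equal(nrow(r$reviewed), 2L) # later candidates never opened

  empty <- all_ok$records[0, ]
  r0 <- sequential_review(case, empty, crit, match_spec())
  expect_length(r0$control_ids, 0L)
  expect_true(r0$exhausted)

  one <- generate_control_stream(
    case, cfg, intended = c("NO_GTUBE", "ELIGIBLE", "INADEQUATE_DATA"))
  r1 <- sequential_review(case, one$records, crit, match_spec(),
                          shuffle = FALSE)
  expect_length(r1$control_ids, 1L)
  expect_true(r1$exhausted)
  expect_equal(r1$n_reviewed_ineligible, 2L)
  # counting accepted charts too
  r1b <- sequential_review(case, one$records, crit, match_spec(),
                           shuffle = FALSE, include_accepted = TRUE)
  expect_equal(r1b$n_reviewed_ineligible, 3L)
})

test_that("matched controls always satisfy the matching constraints", {
  set.seed(42)
  cases <- realize_case_disposition("INCLUDED", cfg, 8)$records
  streams <- list()
  src <- function(case) {
    st <- generate_control_stream(case, cfg, n = 40)
    streams[[as.character(case$patient_id)]] <<- st
    st$records
  }
  mm <- run_matching(cases, src, crit, match_spec())
  expect_true(all(mm$results$n_matched <= 2L))
  for (i in seq_len(nrow(mm$matches))) {
    case <- cases[cases$patient_id == mm$matches$case_id[i], ]
    ctrl <- streams[[mm$matches$case_id[i]]]$records
    ctrl <- ctrl[ctrl$patient_id == mm$matches$control_id[i], ]
    expect_equal(ctrl$sex, case$sex)
    expect_true(abs(as.numeric(ctrl$dob - case$dob)) <= cfg$dob_tolerance_days)
    expect_equal(assess_control(ctrl, crit, case$stone_dx_date), "ELIGIBLE")
  }
  # reviewed tallies account for every opened chart
  expect_equal(sum(mm$tallies$count), nrow(mm$reviewed))
  expect_equal(sum(mm$results$n_reviewed_ineligible) + sum(mm$results$n_matched),
               nrow(mm$reviewed))
})

test_that("without-replacement consumption starves later cases", {
  two_cases <- realize_case_disposition("INCLUDED", cfg, 2)$records
  two_cases$dob <- as.Date(c("2000-06-15", "2000-06-20"))
  two_cases$stone_dx_date <- as.Date(c("2008-06-10", "2008-06-12"))
  shared <- truth_record(patient_id = c("s1", "s2"),
                         dob = as.Date(c("2000-06-17", "2000-06-18")),
                         sex = "M", has_true_stone = FALSE,
                         stone_dx_date = as.Date(NA))
  shared$sex <- two_cases$sex[1]
  two_cases$sex <- shared$sex[1]
  mm <- run_matching(two_cases, shared, crit, match_spec())
  expect_equal(sort(mm$results$n_matched), c(0L, 2L))
  expect_equal(anyDuplicated(mm$matches$control_id), 0L)
  # with replacement both cases reuse the same pair
  mm2 <- run_matching(two_cases, shared, crit, match_spec(replacement = TRUE))
  expect_equal(mm2$results$n_matched, c(2L, 2L))
})

test_that("duplicate case ids are rejected and seeds reproduce matches", {
  cases <- realize_case_disposition("INCLUDED", cfg, 3)$records
  dup <- rbind(cases, cases[1, ])
  expect_error(run_matching(dup, cases[0, ], crit), "duplicate")
  src <- function(case) generate_control_stream(case, cfg, n = 30)$records
  set.seed(500)
  m1 <- run_matching(cases, src, crit, match_spec())
  set.seed(500)
  m2 <- run_matching(cases, src, crit, match_spec())
  expect_identical(m1$matches, m2$matches)
  expect_identical(m1$results$n_reviewed_ineligible,
                   m2$results$n_reviewed_ineligible)
})

test_that("review counts follow the negative-binomial mean at high rates", {
  # with per-review eligibility p, ineligible reviews to reach 2 matches
  # average 2(1-p)/p; checked at p = 0.5 where few candidates are needed
  p <- 0.5
  cfgp <- generator_config(control_stream_eligibility = p, pool_cap = 60)
  case <- realize_case_disposition("INCLUDED", cfgp, 1)$records
  set.seed(321)
  reps <- 400L
  counts <- integer(reps)
  for (r in seq_len(reps)) {
    st <- generate_control_stream(case, cfgp)
    counts[r] <- sequential_review(case, st$records, crit, match_spec(),
                                   shuffle = FALSE)$n_reviewed_ineligible
  }
  expected <- 2 * (1 - p) / p
  se <- stats::sd(counts) / sqrt(reps)
  expect_lt(abs(mean(counts) - expected), 3 * se)
})
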