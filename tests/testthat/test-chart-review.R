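crit <- eligibility_criteria()

test_that("completed-years age uses the birthday-based floor", {
  expect_equal(age_at(as.Date("2000-06-15"), as.Date("2021-06-14")), 20L)
  expect_equal(age_at(as.Date("2000-06-15"), as.Date("2021-06-15")), 21L)
  expect_equal(age_at(as.Date("2000-06-15"), as.Date("2000-06-15")), 0L)
  expect_error(age_at(as.Date("2010-01-02"), as.Date("2010-01-01")),
               "precedes")
})

test_that("age agrees with a calendar-iteration oracle, leap days included", {
  set.seed(11)
  dobs <- c(as.Date("1996-02-29"), as.Date("2000-02-29"),
            as.Date("1990-01-01") + sample.int(8000, 120))
  for (dob in as.list(dobs)) {
    for (on in as.list(dob + sample.int(12000, 4))) {
      expect_equal(age_at(dob, on), age_oracle(dob, on),
                   info = paste(dob, on))
    }
  }
})

test_that("feed-month window counting matches its examples and oracle", {
  expect_equal(feed_months_in_window(c("2009-07", "2009-08", "2009-09"),
                                     as.Date("2010-06-15")), 3L)
  expect_equal(feed_months_in_window(character(0), as.Date("2010-06-15")), 0L)
  # the window includes the index month itself and spans exactly 12 months
  expect_equal(feed_months_in_window("2010-06", as.Date("2010-06-15")), 1L)
  expect_equal(feed_months_in_window("2009-07", as.Date("2010-06-15")), 1L)
  expect_equal(feed_months_in_window("2009-06", as.Date("2010-06-15")), 0L)
  # duplicated tokens count once
  expect_equal(feed_months_in_window(c("2010-01", "2010-01"),
                                     as.Date("2010-06-15")), 1L)
  set.seed(23)
  for (i in 1:200) {
    idx <- as.Date("2004-01-01") + sample.int(3000, 1)
    fm <- ym_token(ym_index(idx) - sample.int(30, sample.int(12, 1),
                                              replace = TRUE) + 10L)
    expect_equal(feed_months_in_window(fm, idx), feed_oracle(fm, idx))
  }
  # list input is the vectorized form of the scalar contract
  fms <- replicate(20, ym_token(ym_index(as.Date("2008-06-01")) -
                                  sample.int(25, 5, replace = TRUE)),
                   simplify = FALSE)
  got <- feed_months_in_window(fms, as.Date("2008-06-01"))
  expect_equal(got, vapply(fms, feed_oracle, integer(1),
                           index_date = as.Date("2008-06-01")))
})

test_that("case screening applies the exclusion rules in precedence order", {
  expect_equal(assess_case(truth_record(), crit), "INCLUDED")
  expect_equal(assess_case(truth_record(has_true_stone = FALSE,
                                        stone_dx_date = as.Date(NA)), crit),
               "NO_STONE")
  expect_equal(assess_case(truth_record(has_true_gtube = FALSE,
                                        gtube_placement_date = as.Date(NA),
                                        feed_months = character(0)), crit),
               "NO_GTUBE")
  expect_equal(assess_case(truth_record(stone_dx_date = as.Date("2003-05-01"),
                                        feed_months = c("2002-11", "2003-01",
                                                        "2003-02", "2003-03")),
                           crit),
               "STUDY_PERIOD")
  expect_equal(assess_case(truth_record(dob = as.Date("1980-03-01")), crit),
               "AGE_RANGE")
  # stone predating G-tube placement
  expect_equal(assess_case(truth_record(
    gtube_placement_date = as.Date("2009-01-01"),
    feed_months = c("2009-01", "2009-02", "2009-03")), crit),
    "ASYNCHRONOUS")
  # too few feed months in the look-back year
  expect_equal(assess_case(truth_record(feed_months = c("2008-01", "2008-02")),
                           crit),
               "ASYNCHRONOUS")
  expect_equal(assess_case(truth_record(nutrition_data_adequate = FALSE),
                           crit),
               "INADEQUATE_DATA")
})

test_that("a record failing several rules takes the first in precedence", {
  rec <- truth_record(has_true_stone = FALSE, stone_dx_date = as.Date(NA),
                      has_true_gtube = FALSE,
                      gtube_placement_date = as.Date(NA),
                      feed_months = character(0),
                      nutrition_data_adequate = FALSE)
  expect_equal(assess_case(rec, crit), "NO_STONE")
  flipped <- c("NO_GTUBE", "NO_STONE", "STUDY_PERIOD", "AGE_RANGE",
               "ASYNCHRONOUS", "INADEQUATE_DATA")
  expect_equal(assess_case(rec, crit, precedence = flipped), "NO_GTUBE")
})

test_that("age bounds are inclusive at both ends of 1-21", {
  rec1 <- truth_record(dob = as.Date("2007-06-10"))  # exactly 1 at index
  expect_equal(age_at(rec1$dob, rec1$stone_dx_date), 1L)
  expect_equal(assess_case(rec1, crit), "INCLUDED")
  rec21 <- truth_record(dob = as.Date("1986-06-11")) # 21 until tomorrow
  expect_equal(age_at(rec21$dob, rec21$stone_dx_date), 21L)
  expect_equal(assess_case(rec21, crit), "INCLUDED")
  rec22 <- truth_record(dob = as.Date("1986-06-10"))
  expect_equal(assess_case(rec22, crit), "AGE_RANGE")
  rec0 <- truth_record(dob = as.Date("2007-06-11"))
  expect_equal(assess_case(rec0, crit), "AGE_RANGE")
})

test_that("control screening anchors on the case's index date", {
  idx <- as.Date("2008-06-10")
  ctrl <- truth_record(has_true_stone = FALSE, stone_dx_date = as.Date(NA))
  expect_equal(assess_control(ctrl, crit, idx), "ELIGIBLE")
  expect_equal(assess_control(
    truth_record(has_true_stone = FALSE, stone_dx_date = as.Date(NA),
                 has_true_gtube = FALSE, gtube_placement_date = as.Date(NA),
                 feed_months = character(0)), crit, idx),
    "NO_GTUBE")
  expect_equal(assess_control(
    truth_record(has_true_stone = FALSE, stone_dx_date = as.Date(NA),
                 nutrition_data_adequate = FALSE), crit, idx),
    "INADEQUATE_DATA")
  # G-tube placed on/after the index date is asynchronous
  expect_equal(assess_control(
    truth_record(has_true_stone = FALSE, stone_dx_date = as.Date(NA),
                 gtube_placement_date = idx,
                 feed_months = c("2008-06", "2008-07", "2008-08")), crit, idx),
    "ASYNCHRONOUS")
  # full 12/12 feed coverage
  full <- truth_record(has_true_stone = FALSE, stone_dx_date = as.Date(NA),
                       feed_months = ym_token(ym_index(idx) - 0:11))
  expect_equal(assess_control(full, crit, idx), "ELIGIBLE")
  expect_error(assess_control(ctrl, crit), "index date")
})

test_that("screening is deterministic and complete", {
  set.seed(5)
  pop <- generate_population(generator_config(n_potential_cases = 60, seed = 5))
  l1 <- assess_case(pop$records, crit)
  l2 <- assess_case(pop$records, crit)
  expect_identical(l1, l2)
  expect_true(all(l1 %in% case_labels()))
  expect_false(anyNA(l1))
})

test_that("adding a feed month never flips an includable record out", {
  set.seed(31)
  pop <- realize_case_disposition("INCLUDED", generator_config(), n = 40)
  rec <- pop$records
  for (i in seq_len(nrow(rec))) {
    extra_month <- ym_token(ym_index(rec$stone_dx_date[i]) -
                              sample.int(14, 1) + 1L)
    extra_month <- max(extra_month, ym_token(ym_index(rec$gtube_placement_date[i])))
    rec$feed_months[[i]] <- union(rec$feed_months[[i]], extra_month)
  }
  expect_true(all(assess_case(rec, crit) == "INCLUDED"))
})

test_that("truth-layer invariants are enforced", {
  bad <- truth_record(has_true_stone = FALSE)  # stone date still present
  expect_error(assess_case(bad, crit), "has_true_stone")
  bad2 <- truth_record(has_true_gtube = FALSE) # placement still present
  expect_error(assess_case(bad2, crit), "has_true_gtube")
  expect_error(assess_case(truth_record()[, -2], crit), "lacks column")
})
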