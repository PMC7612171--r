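test_that("a well-formed cohort validates cleanly", {
  expect_identical(validate_cohort(hand_cohort()), character(0))
})

test_that("violations are reported per subject and rule, never raised", {
  # exposure recorded at a visit after end of follow-up
  bad1 <- sncstm_cohort(list(
    subject_record("x", c(0, 1), c(1, 1), matrix(c(0.5, 0.2), ncol = 1),
                   followup_time = 0.4, event = 1, admin_end = 2)
  ), "L")
  v1 <- validate_cohort(bad1)
  expect_length(grep("subject x.*after end of follow-up", v1), 2L)  # A and L

  # event recorded exactly at the administrative end
  bad2 <- sncstm_cohort(list(
    subject_record("y", 0, 1, matrix(0.5), followup_time = 2, event = 1,
                   admin_end = 2)
  ), "L")
  expect_length(grep("subject y.*administrative censoring", validate_cohort(bad2)), 1L)

  # missing confounder at an attended visit
  bad3 <- sncstm_cohort(list(
    subject_record("z", c(0, 1), c(1, 0), matrix(c(0.5, NA), ncol = 1),
                   followup_time = 2, event = 0, admin_end = 2)
  ), "L")
  expect_length(grep("subject z.*confounder missing", validate_cohort(bad3)), 1L)
})

test_that("crude rates: no events, hand person-time split, scale consistency", {
  r0 <- crude_rates(0, 100, 0, 100)
  expect_identical(r0$rate_treated, 0)
  expect_identical(r0$rate_untreated, 0)
  expect_identical(r0$survival_ratio, 1)
  expect_error(crude_rates(1, 0, 0, 1), "positive")

  # one treated death at t = 1 over 1 py; one untreated survivor over 2 py
  two <- sncstm_cohort(list(
    subject_record("d1", 0, 1, matrix(0), followup_time = 1, event = 1,
                   admin_end = 3),
    subject_record("s1", 0, 0, matrix(0), followup_time = 2, event = 0,
                   admin_end = 2)
  ), "L")
  pt <- person_time_by_exposure(two)
  expect_equal(pt$events_treated, 1)
  expect_equal(pt$py_treated, 1)
  expect_equal(pt$events_untreated, 0)
  expect_equal(pt$py_untreated, 2)
  cr <- do.call(crude_rates, pt)
  expect_equal(cr$rate_treated, 1)
  expect_equal(cr$rate_untreated, 0)
  expect_equal(cr$survival_ratio, exp(-1))

  # multiplying events and person-time by c leaves rates unchanged
  for (c_mult in c(2, 7.5)) {
    expect_equal(crude_rates(74 * c_mult, 3930 * c_mult, 63, 8450)$rate_treated,
                 crude_rates(74, 3930, 63, 8450)$rate_treated)
  }
})

test_that("person-time decomposition sums exactly to total follow-up", {
  sim <- quick_sim(n = 300, seed = 4)
  pt <- person_time_by_exposure(sim$cohort)
  total <- sum(vapply(sim$cohort$records, function(r) r$followup_time,
                      numeric(1)))
  expect_equal(pt$py_treated + pt$py_untreated, total)
})
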