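test_that("choose_delta honours a requested m and the failure-share rule", {
  # single window [0, 10], requested m = 20
  pts <- lapply(1:5, function(i) point_subject(i, 1, 0, T = 10, event = 0))
  coh <- sncstm_cohort(pts, "L")
  expect_equal(choose_delta(coh, m = 20), 0.5)

  # 200 failures evenly spread on [0, 10]: each unit interval holds exactly
  # 10% of them, so delta = 1 is the largest admissible step
  tt <- (seq_len(200) - 0.5) / 20
  coh2 <- sncstm_cohort(
    lapply(seq_along(tt), function(i) point_subject(i, 1, 0, tt[i], 1)), "L")
  expect_equal(choose_delta(coh2, max_fraction = 0.10), 1.0)

  # a window with a single failure can never satisfy the share rule
  coh3 <- sncstm_cohort(list(point_subject(1, 1, 0, 3, 1),
                             point_subject(2, 0, 0, 10, 0)), "L")
  expect_warning(d3 <- choose_delta(coh3), "falling back")
  expect_equal(d3, 0.5)
})

test_that("expansion reproduces the worked single-window examples", {
  coh <- sncstm_cohort(list(
    point_subject("died", 1, 0.3, T = 3.7, event = 1),
    point_subject("survivor", 0, -0.1, T = 10, event = 0),
    point_subject("early", 1, 0.0, T = 0.2, event = 1)
  ), "L")
  ps <- expand_cohort(coh, 0.5)

  died <- ps[ps$subject_id == "died", ]
  expect_equal(nrow(died), 8L)
  expect_equal(died$Q, seq(0, 3.5, by = 0.5))
  expect_equal(died$surv_next, c(rep(1L, 7), 0L))

  surv <- ps[ps$subject_id == "survivor", ]
  expect_equal(nrow(surv), 21L)
  expect_equal(surv$Q, seq(0, 10, by = 0.5))
  # the copy at Q = C has no observable forward interval
  expect_false(surv$outcome_known[21])
  expect_true(all(surv$outcome_known[1:20]))

  early <- ps[ps$subject_id == "early", ]
  expect_equal(nrow(early), 1L)
  expect_equal(early$Q, 0)
  expect_equal(early$surv_next, 0L)
})

test_that("single-window row counts match brute-force enumeration", {
  set.seed(20)
  delta <- 0.5
  for (i in 1:25) {
    T <- round(runif(1, 0, 12), 2)
    ev <- rbinom(1, 1, 0.7)
    C <- 10
    Tc <- min(T, C)
    if (ev == 1 && T >= C) ev <- 0  # administrative rule
    coh <- sncstm_cohort(list(point_subject("s", 1, 0, Tc, ev)), "L")
    ps <- expand_cohort(coh, delta)
    # brute force: count grid points Q = 0, delta, ... with Q <= min(T, C)
    expect_equal(nrow(ps), floor(Tc / delta + 1e-9) + 1,
                 info = paste("T =", T, "event =", ev))
    expect_true(all(ps$T >= ps$Q))
  }
})

test_that("halving delta nests the original grid within each window", {
  sim <- quick_sim(n = 40, seed = 8)
  p1 <- expand_cohort(sim$cohort, 0.2)
  p2 <- expand_cohort(sim$cohort, 0.1)
  k1 <- paste(p1$subject_id, p1$visit_index, round(p1$Q, 9))
  k2 <- paste(p2$subject_id, p2$visit_index, round(p2$Q, 9))
  expect_true(all(k1 %in% k2))
})

test_that("grid re-anchors at visits; short terminal sub-intervals keep their true length", {
  coh <- sncstm_cohort(list(
    subject_record("r", c(0, 1), c(1, 1), matrix(c(0, 0), ncol = 1),
                   followup_time = 2, event = 0, admin_end = 2)
  ), "L")
  ps <- expand_cohort(coh, 0.3)
  w0 <- ps[ps$visit_index == 0, ]
  expect_equal(w0$Q, c(0, 0.3, 0.6, 0.9))
  expect_equal(w0$delta_row, c(0.3, 0.3, 0.3, 0.1), tolerance = 1e-12)
  w1 <- ps[ps$visit_index == 1, ]
  # boundary grid point lands in the later window as its anchor
  expect_equal(w1$Q[1], 1)
  expect_equal(w1$Q, c(1, 1.3, 1.6, 1.9))
  # no row claims a known outcome beyond the status horizon
  expect_true(all(ps$T[ps$outcome_known] + 1e-9 >=
                    (ps$Q + ps$delta_row)[ps$outcome_known] |
                    ps$event[ps$outcome_known] == 1L))
})

test_that("a step at least as large as the narrowest window is refused", {
  expect_error(expand_cohort(hand_cohort(), 1.0), "skip a window")
  expect_error(expand_cohort(hand_cohort(), 1.7), "skip a window")
})
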