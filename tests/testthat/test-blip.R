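test_that("blip_spec builds ids, shares by lag, and rejects cross-lag merges", {
  sp <- blip_spec(2)
  expect_equal(nrow(sp$params), 6L)  # (k, l) pairs with k <= l <= 2
  expect_setequal(sp$parameter_ids,
                  c("psi_0(0)", "psi_1(1)", "psi_2(2)",
                    "psi_0(1)", "psi_1(2)", "psi_0(2)"))
  spl <- blip_spec(2, sharing = "by_lag")
  expect_setequal(spl$parameter_ids, c("psi_lag0", "psi_lag1", "psi_lag2"))
  spm <- blip_spec(1, modifiers = "L")
  expect_setequal(spm$parameter_ids,
                  c("psi_0(0)", "psi_1(1)", "psi_0(1)",
                    "psi_0(0):L", "psi_1(1):L", "psi_0(1):L"))
  expect_error(blip_spec(1, sharing = function(k, l, basis) "one"),
               "unequal lag")
})

test_that("cumulative blip evaluates the piecewise-linear sum", {
  rec <- subject_record("h", c(0, 1, 2), c(1, 1, 0),
                        matrix(c(0.2, -0.1, 0.5), ncol = 1,
                               dimnames = list(NULL, "L")),
                        followup_time = 4, event = 0, admin_end = 4)
  sp <- blip_spec(2)
  psi <- setNames(rep(0.07, 6), sp$parameter_ids)
  psi["psi_1(1)"] <- 0.2
  psi["psi_1(2)"] <- 0.1

  # no elapsed time at the exposure's own visit
  expect_equal(cumulative_blip(psi, rec, sp, 1, t = 1), 0)
  # hand value: 0.2 * (s_2 - s_1) + 0.1 * (2.5 - s_2)
  expect_equal(cumulative_blip(psi, rec, sp, 1, t = 2.5), 0.25)
  # single post-baseline visit reduces to A_1 * psi_1 * (t - s_1)
  rec1 <- subject_record("h1", c(0, 1), c(0, 1),
                         matrix(c(0, 0), ncol = 1, dimnames = list(NULL, "L")),
                         followup_time = 2, event = 0, admin_end = 2)
  sp1 <- blip_spec(1)
  psi1 <- setNames(c(0.3, 0.25, 0.1), sp1$parameter_ids)
  expect_equal(cumulative_blip(psi1, rec1, sp1, 1, t = 1.8),
               psi1[["psi_1(1)"]] * 0.8)
  expect_error(cumulative_blip(psi, rec, sp, 1, t = 0.5), "must be >=")
})

test_that("blipped outcomes transform the indicator as specified", {
  sim <- quick_sim(n = 50, seed = 60)
  ps <- expand_cohort(sim$cohort, 0.5)
  sp <- blip_spec(1)
  psi <- setNames(c(0.2, 0.3, 0.1), sp$parameter_ids)
  w1 <- ps[ps$visit_index == 1 & ps$outcome_known, ]

  # immediate effect (k = l): the raw indicator, untouched
  expect_equal(blip_outcome(w1[1, ], psi, sp, k = 1, l = 1),
               w1$surv_next[1])

  # delayed effect: survivor with A_1 = 1, psi_1 = 0.3, step 0.5 -> exp(0.15)
  surv_row <- w1[w1$surv_next == 1 & w1$A_1 == 1 & w1$delta_row == 0.5, ][1, ]
  expect_equal(blip_outcome(surv_row, psi, sp, k = 0, l = 1), exp(0.15))

  # a death before Q + delta gives zero whatever psi is
  dead_row <- w1[w1$surv_next == 0, ][1, ]
  expect_equal(blip_outcome(dead_row, psi, sp, k = 0, l = 1), 0)

  # missing required parameter is a named error
  expect_error(blip_outcome(surv_row, psi[-2], sp, k = 0, l = 1),
               "psi_1\\(1\\)")
})

test_that("propensity residuals satisfy the weighted normal equations", {
  sim <- quick_sim(n = 500, seed = 61)
  ps <- expand_cohort(sim$cohort, 0.1)
  sp <- blip_spec(1)
  pf <- fit_propensity_window(ps, k = 0, l = 0, psi_prior = numeric(0),
                              spec = sp, control = sncstm_control())
  rows <- ps[pf$rows, ]
  # orthogonality to the intercept and to the elapsed-time covariate
  expect_lt(abs(sum(pf$weights * pf$residuals)), 1e-8)
  expect_lt(abs(sum(pf$weights * pf$residuals * rows$Q)), 1e-8)
  expect_lt(abs(sum(pf$weights * pf$residuals * rows$L_0)), 1e-8)
  # lag-0 fits carry unit working weights (no blip, no censoring)
  expect_true(all(pf$weights == 1))
})

test_that("lag estimation returns zero when all outcomes are one, flags empty windows", {
  # no failures, no censoring before C: all usable outcomes are 1
  recs <- lapply(1:40, function(i) {
    subject_record(i, c(0, 1), c(rbinom(1, 1, 0.5), rbinom(1, 1, 0.5)),
                   matrix(rnorm(2), ncol = 1), followup_time = 2, event = 0,
                   admin_end = 2)
  })
  coh <- sncstm_cohort(recs, "L")
  ps <- expand_cohort(coh, 0.25)
  sp <- blip_spec(1)
  l0 <- estimate_lag(ps, 0, numeric(0), sp, sncstm_control())
  expect_equal(unname(l0$psi), c(0, 0))

  # a window with no rows is inestimable, not an exception
  short <- sncstm_cohort(lapply(1:30, function(i) {
    subject_record(i, c(0, 1), c(rbinom(1, 1, 0.5), NA), matrix(c(rnorm(1), NA)),
                   followup_time = runif(1, 0.1, 0.9),
                   event = 1, admin_end = 2)
  }), "L")
  fit <- suppressWarnings(fit_sncstm(short, sp, sncstm_control(delta = 0.2)))
  expect_true(is.na(fit$psi["psi_1(1)"]))
  expect_true(any(grepl("inestimable", fit$warnings)))
})
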