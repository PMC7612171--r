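test_that("counterfactual curve is 1 at t = 0 and unadjusted when psi is zero", {
  sim <- quick_sim(n = 400, seed = 90)
  fit <- suppressWarnings(fit_sncstm(sim$cohort, blip_spec(1),
                                     sncstm_control(delta = 0.1)))
  fit$psi[] <- 0
  tt <- c(0, 0.8, 1.5, 2)
  cv <- counterfactual_survival(sim$cohort, fit, tt)
  expect_identical(cv$estimate[1], 1)
  Tf <- vapply(sim$cohort$records, function(r) r$followup_time, numeric(1))
  # with psi = 0 and no dropout this is the empirical proportion with T >= t
  expect_equal(cv$estimate, vapply(tt, function(t) mean(Tf >= t), numeric(1)))
  expect_error(counterfactual_survival(sim$cohort, fit, 2.5),
               "administrative end")
})

test_that("observed curve matches hand-computed product-limit values", {
  coh <- sncstm_cohort(list(
    point_subject(1, 0, 0, T = 1, event = 1, C = 5),
    point_subject(2, 0, 0, T = 2, event = 0, C = 5),
    point_subject(3, 0, 0, T = 3, event = 1, C = 5),
    point_subject(4, 0, 0, T = 4, event = 1, C = 5),
    point_subject(5, 0, 0, T = 5, event = 0, C = 5)
  ), "L")
  ob <- observed_survival(coh, c(0, 1, 2.5, 3.5, 5))
  # P(T >= t): left limits of the Kaplan-Meier step function
  expect_equal(ob$estimate,
               c(1, 1, 4 / 5, 4 / 5 * 2 / 3, 4 / 5 * 2 / 3 * 1 / 2))
})

test_that("estimates above one are reported, never clipped, with a warning", {
  coh <- sncstm_cohort(lapply(1:12, function(i) {
    point_subject(i, 1, 0, T = 3, event = 0, C = 3)
  }), "L")
  fake <- structure(
    list(psi = c(`psi_0(0)` = 0.4), delta = 0.5, spec = blip_spec(0),
         censoring_model = NULL),
    class = "sncstm_fit")
  expect_warning(cv <- counterfactual_survival(coh, fake, c(0, 2)),
                 "exceeds 1")
  expect_equal(cv$estimate[2], exp(0.4 * 2))
})

test_that("counterfactual and observed curves agree under zero blips without dropout", {
  sim <- quick_sim(n = 500, seed = 91, psi = rbind(c(0, 0), c(NA, 0)))
  fit <- suppressWarnings(fit_sncstm(sim$cohort, blip_spec(1),
                                     sncstm_control(delta = 0.1)))
  fit$psi[] <- 0
  # grid points chosen away from observed failure times
  tt <- c(0.45, 1.25, 1.95)
  cv <- counterfactual_survival(sim$cohort, fit, tt)
  ob <- observed_survival(sim$cohort, tt)
  expect_equal(cv$estimate, ob$estimate, tolerance = 1e-10)
})
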