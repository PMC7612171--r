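test_that("zero structural blips couple factual and counterfactual times exactly", {
  cfg <- sim_config(n = 2000, psi = rbind(c(0, 0), c(NA, 0)))
  sim <- simulate_cohort(cfg, seed = 40)
  # hazards agree algebraically; times agree to floating-point association order
  expect_lt(max(abs(sim$oracle$T_factual - sim$oracle$T_zero)), 1e-10)
  os <- oracle_survival_zero(sim$oracle, seq(0, 2, by = 0.25))
  expect_true(all(diff(os$survival) <= 0))
})

test_that("constant hazard reproduces exponential survival", {
  cfg <- sim_config(n = 10000, visit_times = 0, admin_end = 5,
                    h0 = 0.2, beta_L = 0, gamma = 0, psi = matrix(0),
                    exposure_coefs = c(intercept = 0, L = 0, A_prev = 0))
  sim <- simulate_cohort(cfg, seed = 41)
  ev <- mean(vapply(sim$cohort$records, function(r) r$event, integer(1)))
  # P(T <= 5) = 1 - exp(-0.2 * 5); binomial MC sd ~ 0.005
  expect_equal(ev, 1 - exp(-1), tolerance = 0.02)
  os <- oracle_survival_zero(sim$oracle, c(1, 2.5))
  expect_equal(os$survival, exp(-0.2 * c(1, 2.5)), tolerance = 0.02)
})

test_that("the generator is deterministic under a fixed seed", {
  cfg <- sim_config(n = 300, dropout = c(intercept = -2, L = 0.3, A = 0.2))
  s1 <- simulate_cohort(cfg, seed = 42)
  s2 <- simulate_cohort(cfg, seed = 42)
  expect_identical(s1$oracle, s2$oracle)
  expect_identical(s1$cohort$records, s2$cohort$records)
})

test_that("negative hazards trigger the floor warning", {
  cfg <- sim_config(n = 500, h0 = 0.05, beta_L = 0.6)
  expect_warning(simulate_cohort(cfg, seed = 43), "floored")
})

test_that("true_psi maps the matrix onto parameter ids and checks sharing", {
  cfg <- sim_config(psi = rbind(c(0.1, 0.05), c(NA, 0.15)))
  tp <- true_psi(cfg)
  expect_equal(tp[["psi_0(0)"]], 0.10)
  expect_equal(tp[["psi_1(1)"]], 0.15)
  expect_equal(tp[["psi_0(1)"]], 0.05)
  expect_error(true_psi(cfg, blip_spec(1, sharing = "by_lag")),
               "unequal true values")
  cfg_eq <- sim_config(psi = rbind(c(0.1, 0.05), c(NA, 0.1)))
  tps <- true_psi(cfg_eq, blip_spec(1, sharing = "by_lag"))
  expect_equal(unname(tps), c(0.1, 0.05))
})
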