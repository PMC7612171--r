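test_that("point-exposure fit matches an independently coded five-step oracle", {
  # K = 0 cohort: the pipeline must reduce exactly to the point-exposure
  # procedure (expand, propensity with Q, gamma score with covariate
  # -residual * delta), coded here from scratch with stats::glm + uniroot.
  set.seed(70)
  n <- 400
  L <- rnorm(n)
  A <- rbinom(n, 1, plogis(-0.3 + 0.8 * L))
  C <- 5
  haz <- pmax(0.15 + 0.05 * L + 0.12 * A, 0.01)
  Tf <- rexp(n) / haz
  Tobs <- pmin(Tf, C)
  ev <- as.integer(Tf <= C)
  coh <- sncstm_cohort(lapply(1:n, function(i) {
    point_subject(i, A[i], L[i], Tobs[i], ev[i], C = C)
  }), "L")

  delta <- 0.25
  fit <- fit_sncstm(coh, blip_spec(0), sncstm_control(delta = delta))

  # oracle: explicit expansion and scalar score root
  Q <- unlist(lapply(1:n, function(i) seq(0, Tobs[i], by = delta)))
  id <- rep(1:n, vapply(1:n, function(i) length(seq(0, Tobs[i], by = delta)),
                        integer(1)))
  pr <- suppressWarnings(
    glm(A[id] ~ L[id] + Q, family = binomial())
  )
  Dhat <- A[id] - fitted(pr)
  keep <- Q + delta <= C & (ev[id] == 1L | Tobs[id] >= Q + delta)
  y <- as.numeric(Tobs[id] >= Q + delta)[keep]
  z <- (-Dhat * delta)[keep]
  root <- uniroot(function(p) sum(z * (y * exp(-z * p) - 1)),
                  c(-5, 5), tol = 1e-12)$root
  expect_equal(unname(fit$psi), root, tolerance = 1e-7)
  expect_lt(fit$diagnostics$lag0[[1]]$score_norm, 1e-8)
})

test_that("with all blips zero the working weights collapse to censoring weights", {
  sim <- quick_sim(n = 200, seed = 71)
  ps <- expand_cohort(sim$cohort, 0.2)
  sp <- blip_spec(1)
  psi0 <- setNames(rep(0, 3), sp$parameter_ids)
  pf <- fit_propensity_window(ps, k = 0, l = 1, psi_prior = psi0,
                              spec = sp, control = sncstm_control())
  rows <- ps[pf$rows, ]
  expect_identical(pf$weights, rows$work_weight)
  expect_true(all(pf$weights > 0))
})

test_that("parameter sharing by lag stacks windows into a single score equation", {
  sim <- quick_sim(n = 500, seed = 72,
                   psi = rbind(c(0.12, 0.05), c(NA, 0.12)))
  spl <- blip_spec(1, sharing = "by_lag")
  fit <- suppressWarnings(fit_sncstm(sim$cohort, spl,
                                     sncstm_control(delta = 0.1)))
  expect_named(fit$psi, c("psi_lag0", "psi_lag1"))
  expect_true(all(is.finite(fit$psi)))
  # the stacked lag-0 estimate sits between the two unshared ones
  fu <- suppressWarnings(fit_sncstm(sim$cohort, blip_spec(1),
                                    sncstm_control(delta = 0.1)))
  expect_gte(fit$psi["psi_lag0"], min(fu$psi[c("psi_0(0)", "psi_1(1)")]) - 1e-9)
  expect_lte(fit$psi["psi_lag0"], max(fu$psi[c("psi_0(0)", "psi_1(1)")]) + 1e-9)
})

test_that("bootstrap honours B = 0 and is reproducible under a fixed seed", {
  sim <- quick_sim(n = 150, seed = 73)
  fit <- suppressWarnings(fit_sncstm(sim$cohort, blip_spec(1),
                                     sncstm_control(delta = 0.2)))
  f0 <- bootstrap_sncstm(sim$cohort, fit, B = 0)
  expect_null(f0$boot$se)
  expect_equal(f0$boot$B, 0L)

  f1 <- suppressWarnings(bootstrap_sncstm(sim$cohort, fit, B = 8, seed = 99))
  f2 <- suppressWarnings(bootstrap_sncstm(sim$cohort, fit, B = 8, seed = 99))
  expect_identical(f1$boot$se, f2$boot$se)
  expect_identical(f1$boot$ci, f2$boot$ci)
})
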