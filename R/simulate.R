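#' Configuration for the synthetic-cohort generator
#'
#' Describes a longitudinal cohort with time-varying confounding: a scalar
#' confounder `L` measured at each visit follows an autoregression driven by
#' the previous exposure (`L_k = rho * L_{k-1} + gamma * A_{k-1} + noise`),
#' the exposure at each visit depends on the current confounder and the
#' previous exposure, and the failure hazard is additive in the current
#' confounder and the exposure history. `gamma != 0` together with
#' `beta_L != 0` creates genuine time-varying confounding: `L_k` confounds
#' the later exposure while sitting on a causal pathway from the earlier one.
#'
#' `psi` holds the TRUE structural blip parameters, i.e. exactly the
#' quantities the g-estimator targets: `psi[k+1, l+1]` is the causal effect
#' of `A_k` on the hazard in window `[s_l, s_{l+1})` when all later exposures
#' are set to zero — a controlled direct effect that controls later
#' *exposures only*, so for `l > k` it includes the pathway through the
#' confounder (`A_k` shifts `L_l` by `gamma * rho^(l-k-1)`). The generator
#' therefore uses hazard coefficients
#' `psi[k, l] - beta_L * gamma * rho^(l-k-1)` for `l > k` (and `psi[k, k]`
#' on the diagonal), which makes the structural blip equations hold exactly
#' by construction; see the methods vignette for the derivation.
#'
#' @param n Cohort size.
#' @param visit_times Common visit schedule `s_0 = 0 < ... < s_K`.
#' @param admin_end Administrative censoring time `C > s_K`.
#' @param exposure_type `"binary"` (logistic exposure model) or
#'   `"continuous"` (linear-Gaussian).
#' @param exposure_coefs Named vector `c(intercept, L, A_prev)` of the
#'   exposure model on the linear-predictor scale.
#' @param exposure_sd Residual SD for a continuous exposure.
#' @param rho,gamma,L_sd Confounder autoregression, effect of the previous
#'   exposure on the confounder, and innovation SD (`L_0` is standard
#'   normal).
#' @param h0,beta_L Baseline hazard level and effect of the current
#'   confounder on the hazard.
#' @param psi Upper-triangular `(K+1) x (K+1)` matrix of true structural
#'   blips (scalars are recycled onto the whole upper triangle).
#' @param dropout `NULL` for administrative censoring only, or a named
#'   vector `c(intercept, L, A)` of log-hazard coefficients for a
#'   covariate-dependent dropout process.
#' @param seed Default seed used by [simulate_cohort()] when none is given.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n = 2000L,
                       visit_times = c(0, 1),
                       admin_end = 2,
                       exposure_type = c("binary", "continuous"),
                       exposure_coefs = c(intercept = -1, L = 0.8, A_prev = 1.5),
                       exposure_sd = 1,
                       rho = 0.8, gamma = 0.5, L_sd = 0.5,
                       h0 = 0.4, beta_L = 0.1,
                       psi = rbind(c(0.10, 0.05), c(NA, 0.15)),
                       dropout = NULL, seed = NULL) {
  exposure_type <- match.arg(exposure_type)
  K <- length(visit_times) - 1L
  stopifnot(visit_times[1L] == 0, admin_end > visit_times[K + 1L])
  if (length(psi) == 1L) {
    psi <- matrix(psi, K + 1L, K + 1L)
  }
  psi <- as.matrix(psi)
  if (!all(dim(psi) == K + 1L)) {
    stop("psi must be a (K+1) x (K+1) matrix matching visit_times")
  }
  psi[lower.tri(psi)] <- NA_real_
  structure(
    list(n = as.integer(n), visit_times = visit_times, admin_end = admin_end,
         exposure_type = exposure_type, exposure_coefs = exposure_coefs,
         exposure_sd = exposure_sd, rho = rho, gamma = gamma, L_sd = L_sd,
         h0 = h0, beta_L = beta_L, psi = psi, dropout = dropout, seed = seed),
    class = "sim_config"
  )
}

#' True structural blip parameters as a named vector
#'
#' Maps the simulator's `psi` matrix onto the parameter ids of a
#' [blip_spec()] (no modifiers). With `sharing = "by_lag"` the per-lag
#' values must agree across visits, otherwise an error is raised.
#'
#' @param config A [sim_config()].
#' @param spec A [blip_spec()] with the same `K`; default unshared spec.
#' @return Named numeric vector keyed by parameter id.
#' @export
true_psi <- function(config, spec = NULL) {
  K <- length(config$visit_times) - 1L
  if (is.null(spec)) spec <- blip_spec(K)
  if (length(spec$modifiers)) stop("simulator has no effect modifiers")
  pt <- spec$params
  out <- stats::setNames(rep(NA_real_, length(spec$parameter_ids)),
                         spec$parameter_ids)
  for (i in seq_len(nrow(pt))) {
    v <- config$psi[pt$k[i] + 1L, pt$l[i] + 1L]
    if (!is.na(out[pt$id[i]]) && abs(out[pt$id[i]] - v) > 1e-12) {
      stop("sharing map merges unequal true values for id ", pt$id[i])
    }
    out[pt$id[i]] <- v
  }
  out
}

# hazard coefficient of A_k in window l implied by the structural blips
hazard_coef <- function(config, k, l) {
  v <- config$psi[k + 1L, l + 1L]
  if (l > k) v <- v - config$beta_L * config$gamma * config$rho^(l - k - 1L)
  v
}

#' Simulate a cohort with time-varying confounding and coupled counterfactuals
#'
#' Generates confounder/exposure paths and a failure time from the
#' piecewise-constant additive hazard, by inverting the cumulative hazard at
#' a single uniform draw per subject. The same uniform — and the same
#' confounder innovations — are reused with all exposures forced to zero to
#' produce the coupled counterfactual time `T(0)` reported in the oracle
#' table; with all structural blips zero the two hazards cancel exactly and
#' the factual and counterfactual times coincide. Negative hazard values are
#' floored at zero; a warning is raised if the floor is hit on more than 1%
#' of the evaluated (subject, window) pairs, since flooring breaks the exact
#' multiplicative survival structure.
#'
#' Optional covariate-dependent dropout is generated from a log-linear
#' hazard in the current confounder and exposure; the recorded follow-up
#' time is the minimum of failure, dropout and the administrative end.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; overrides `config$seed`.
#' @return List with `cohort` (an [sncstm_cohort()]) and `oracle`
#'   (`data.frame` of `subject_id`, `T_factual`, `T_zero`, uncensored).
#' @export
simulate_cohort <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(seed)) seed <- config$seed
  if (!is.null(seed)) set.seed(seed)
  n <- config$n
  s <- config$visit_times
  K <- length(s) - 1L
  C <- config$admin_end
  ec <- config$exposure_coefs

  # common random numbers: innovations and draws for every visit, all subjects
  eps <- matrix(stats::rnorm(n * (K + 1L)), n, K + 1L)  # L_0 standard normal
  if (K >= 1L) eps[, -1L] <- eps[, -1L, drop = FALSE] * config$L_sd
  u_expo <- matrix(stats::runif(n * (K + 1L)), n, K + 1L)
  u_fail <- stats::runif(n)
  u_drop <- stats::runif(n)

  Lf <- L0 <- matrix(NA_real_, n, K + 1L)  # factual / all-exposures-removed
  Af <- matrix(NA_real_, n, K + 1L)
  for (k in 0:K) {
    if (k == 0L) {
      Lf[, 1L] <- eps[, 1L]
      L0[, 1L] <- eps[, 1L]
    } else {
      Lf[, k + 1L] <- config$rho * Lf[, k] + config$gamma * Af[, k] + eps[, k + 1L]
      L0[, k + 1L] <- config$rho * L0[, k] + eps[, k + 1L]
    }
    lp <- ec[["intercept"]] + ec[["L"]] * Lf[, k + 1L] +
      if (k > 0L) ec[["A_prev"]] * Af[, k] else 0
    Af[, k + 1L] <- if (config$exposure_type == "binary") {
      as.numeric(u_expo[, k + 1L] < stats::plogis(lp))
    } else {
      lp + config$exposure_sd * stats::qnorm(u_expo[, k + 1L])
    }
  }

  # piecewise-constant hazards per window; terminal window extends past C so
  # that uncensored counterfactual times are always defined
  bounds <- c(s, Inf)
  hf <- h0m <- matrix(NA_real_, n, K + 1L)
  for (l in 0:K) {
    acc <- config$h0 + config$beta_L * Lf[, l + 1L]
    for (k in 0:l) acc <- acc + Af[, k + 1L] * hazard_coef(config, k, l)
    hf[, l + 1L] <- acc
    h0m[, l + 1L] <- config$h0 + config$beta_L * L0[, l + 1L]
  }
  floor_frac <- (sum(hf < 0) + sum(h0m < 0)) / (2 * n * (K + 1L))
  if (floor_frac > 0.01) {
    warning("hazard floored at 0 on ", signif(100 * floor_frac, 3),
            "% of (subject, window) evaluations; the additive-hazard ",
            "structure is distorted there")
  }
  hf <- pmax(hf, 0)
  h0m <- pmax(h0m, 0)

  invert_time <- function(H, u) {
    E <- -log(u)
    Tt <- rep(Inf, n)
    cum <- rep(0, n)
    for (l in 0:K) {
      len <- bounds[l + 2L] - bounds[l + 1L]
      add <- H[, l + 1L] * len           # Inf * 0-hazard handled below
      add[H[, l + 1L] == 0] <- 0
      hit <- is.infinite(Tt) & (cum + add >= E)
      Tt[hit] <- bounds[l + 1L] + (E[hit] - cum[hit]) / H[hit, l + 1L]
      cum <- cum + add
    }
    Tt
  }
  T_fail <- invert_time(hf, u_fail)
  T_zero <- invert_time(h0m, u_fail)

  T_drop <- rep(Inf, n)
  if (!is.null(config$dropout)) {
    dc <- config$dropout
    hd <- matrix(NA_real_, n, K + 1L)
    for (l in 0:K) {
      hd[, l + 1L] <- exp(dc[["intercept"]] + dc[["L"]] * Lf[, l + 1L] +
                            dc[["A"]] * Af[, l + 1L])
    }
    T_drop <- invert_time(hd, u_drop)
  }

  T_obs <- pmin(T_fail, T_drop, C)
  event <- as.integer(T_fail <= pmin(T_drop, C))

  cov_name <- "L"
  records <- vector("list", n)
  for (i in seq_len(n)) {
    attended <- s <= T_obs[i] & !(event[i] == 1L & s == T_obs[i])
    a <- ifelse(attended, Af[i, ], NA_real_)
    l <- ifelse(attended, Lf[i, ], NA_real_)
    records[[i]] <- subject_record(
      subject_id = as.character(i), visit_times = s,
      exposures = a, confounders = matrix(l, ncol = 1L,
                                          dimnames = list(NULL, cov_name)),
      followup_time = T_obs[i], event = event[i], admin_end = C
    )
  }
  list(
    cohort = sncstm_cohort(records, cov_name),
    oracle = data.frame(subject_id = as.character(seq_len(n)),
                        T_factual = T_fail, T_zero = T_zero,
                        stringsAsFactors = FALSE)
  )
}

#' Oracle counterfactual survival curve
#'
#' Empirical survival function of the coupled counterfactual failure times
#' `T(0)` from [simulate_cohort()], with no censoring applied — the ground
#' truth against which [counterfactual_survival()] is validated.
#'
#' @param oracle The oracle table returned by [simulate_cohort()].
#' @param times Evaluation times.
#' @return `data.frame` with columns `time` and `survival`.
#' @export
oracle_survival_zero <- function(oracle, times) {
  data.frame(
    time = times,
    survival = vapply(times, function(t) mean(oracle$T_zero >= t), numeric(1))
  )
}

#' Naive regression-adjusted comparator (biased under time-varying confounding)
#'
#' The standard—invalid—alternative to g-estimation: a linear model of the
#' interval death indicator on all exposures and all measured confounders,
#' fitted per window on the expanded data and rescaled by the interval
#' length. Adjusting for post-exposure confounders blocks the part of an
#' earlier exposure's effect that runs through them, so the delayed-effect
#' coefficients are biased for the structural blips whenever the confounder
#' both responds to exposure and affects the hazard. Provided as the
#' contrast arm for validation experiments.
#'
#' @param cohort An [sncstm_cohort()] with a common visit schedule.
#' @param delta Grid step for the expansion.
#' @return Matrix `naive[k+1, l+1]` of per-window exposure coefficients on
#'   the hazard scale.
#' @export
naive_adjusted_fit <- function(cohort, delta) {
  pseudo <- expand_cohort(cohort, delta)
  cov_names <- attr(pseudo, "covariate_names")
  Kmax <- attr(pseudo, "Kmax")
  out <- matrix(NA_real_, Kmax + 1L, Kmax + 1L)
  for (l in 0:Kmax) {
    rows <- pseudo[pseudo$visit_index == l & pseudo$outcome_known &
                     pseudo$delta_row > 0, , drop = FALSE]
    if (!nrow(rows)) next
    X <- cbind(`(Intercept)` = rep(1, nrow(rows)))
    for (k in 0:l) {
      X <- cbind(X, rows[[paste0("A_", k)]])
      colnames(X)[ncol(X)] <- paste0("A_", k)
    }
    for (k in 0:l) {
      for (cn in cov_names) {
        X <- cbind(X, rows[[paste0(cn, "_", k)]])
        colnames(X)[ncol(X)] <- paste0(cn, "_", k)
      }
    }
    # death probability over the interval, per unit time
    y <- (1 - rows$surv_next) / rows$delta_row
    fit <- stats::lm.wfit(X, y, w = rep(1, nrow(rows)))
    for (k in 0:l) out[k + 1L, l + 1L] <- fit$coefficients[paste0("A_", k)]
  }
  out
}
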