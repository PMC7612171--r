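#' Counterfactual survival curve under removal of all exposures
#'
#' Estimates `P{T(0) >= t}`, the probability of surviving to `t` had every
#' exposure been set to zero, as the (weighted) average over subjects of the
#' adjusted survival indicator
#' `I(T >= t) * exp{ sum_k H_k(t; psi_hat) }`,
#' where the sum runs over the subject's attended visits with `s_k <= t` and
#' `H_k` is the cumulative blip of [cumulative_blip()]. Subjects
#' dropout-censored before `min(t, T)` are excluded and, when a censoring
#' model is available, the remaining subjects are weighted by one over their
#' estimated probability of being uncensored at `min(t, T)`. Without dropout
#' all weights are 1.
#'
#' The multiplicative survival model does not constrain the estimate below 1;
#' values above 1 are reported as-is with a warning, never clipped.
#'
#' @param cohort The [sncstm_cohort()] the model was fitted to.
#' @param fit An [fit_sncstm()] result (supplies `psi`, `delta`, the blip
#'   spec and any censoring model).
#' @param times Numeric vector of evaluation times, all within `[0, C]`.
#' @param normalization `"hajek"` divides by the sum of weights over included
#'   subjects (default); `"n"` divides by the full cohort size. The two
#'   coincide when there is no dropout.
#' @return `data.frame` with columns `time`, `estimate`, `n_included`,
#'   `sum_weights`.
#' @export
counterfactual_survival <- function(cohort, fit, times,
                                    normalization = c("hajek", "n")) {
  stopifnot(inherits(cohort, "sncstm_cohort"), inherits(fit, "sncstm_fit"))
  normalization <- match.arg(normalization)
  C_min <- min(vapply(cohort$records, function(r) r$admin_end, numeric(1)))
  if (any(times > C_min)) {
    stop("evaluation times must not exceed the administrative end (",
         C_min, ")")
  }
  if (any(times < 0)) stop("evaluation times must be non-negative")
  psi <- fit$psi
  spec <- fit$spec
  n <- length(cohort$records)

  # per-subject log of estimated probability of remaining uncensored at x
  log_p_unc <- NULL
  if (!is.null(fit$censoring_model) && !is.null(fit$censoring_model$fit)) {
    pseudo <- expand_cohort(cohort, fit$delta)
    cm <- fit_censoring_model(pseudo, covariates = fit$censoring_model$covariates)
    log_p_unc <- function(i, x) {
      sel <- pseudo$subject_id == cohort$records[[i]]$subject_id &
        pseudo$Q + pseudo$delta_row <= x + 1e-12
      sum(log1p(-cm$hazards[sel]))
    }
  }

  out <- data.frame(time = times, estimate = NA_real_,
                    n_included = NA_integer_, sum_weights = NA_real_)
  any_above_one <- FALSE
  for (ti in seq_along(times)) {
    t <- times[ti]
    num <- 0; den <- 0; n_inc <- 0L
    for (i in seq_len(n)) {
      r <- cohort$records[[i]]
      dropout <- r$event == 0L && r$followup_time < r$admin_end
      if (dropout && r$followup_time < t) next  # status at t unknown
      w <- if (is.null(log_p_unc)) 1 else
        exp(-log_p_unc(i, min(t, r$followup_time)))
      ind <- as.numeric(r$followup_time >= t)
      contrib <- 0
      if (ind > 0) {
        s <- r$visit_times
        H <- 0
        for (k in 0:(length(s) - 1L)) {
          if (s[k + 1L] > t) break
          if (is.na(r$exposures[k + 1L])) next
          H <- H + cumulative_blip(psi, r, spec, k, t)
        }
        contrib <- exp(H)
      }
      num <- num + w * contrib
      den <- den + w
      n_inc <- n_inc + 1L
    }
    est <- if (normalization == "hajek") num / den else num / n
    if (is.finite(est) && est > 1) any_above_one <- TRUE
    out$estimate[ti] <- est
    out$n_included[ti] <- n_inc
    out$sum_weights[ti] <- den
  }
  if (any_above_one) {
    warning("counterfactual survival estimate exceeds 1 at some time(s); ",
            "the multiplicative model does not bound probabilities by 1")
  }
  out
}

#' Observed-regime survival curve
#'
#' Kaplan-Meier estimate of `P(T >= t)` under the exposure regime actually
#' followed in the cohort, treating dropout and administrative censoring
#' alike as censoring events. Because the product-limit estimator is
#' right-continuous (`P(T > t)` at event times), the left limit is evaluated
#' so that an event exactly at `t` still counts as surviving *to* `t`.
#'
#' @param cohort An [sncstm_cohort()].
#' @param times Evaluation times.
#' @return `data.frame` with columns `time` and `estimate`.
#' @export
observed_survival <- function(cohort, times) {
  stopifnot(inherits(cohort, "sncstm_cohort"))
  Tf <- vapply(cohort$records, function(r) r$followup_time, numeric(1))
  ev <- vapply(cohort$records, function(r) r$event, integer(1))
  sf <- survival::survfit(survival::Surv(Tf, ev) ~ 1)
  eps <- max(Tf) * 1e-9
  tm <- pmax(times - eps, 0)
  sm <- summary(sf, times = tm, extend = TRUE)
  data.frame(time = times, estimate = sm$surv)
}
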