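#' Control parameters for SNCSTM fitting
#'
#' @param delta Grid step; if `NULL`, chosen by [choose_delta()] (or from `m`).
#' @param m If given (and `delta` is `NULL`), use step = smallest window / `m`.
#' @param max_fraction,fallback_m Passed to [choose_delta()].
#' @param propensity_family `"binomial"`, `"gaussian"` or `NULL` to pick
#'   automatically (logit for 0/1 exposures, linear otherwise).
#' @param history `"full"` regresses the exposure at visit `k` on all
#'   confounders measured at visits `0..k` and all earlier exposures;
#'   `"current"` uses only the visit-`k` confounders and the previous
#'   exposure.
#' @param ipcw Model covariate-dependent dropout and apply inverse
#'   probability of censoring weights to both the propensity and score fits.
#' @param censoring_covariates Covariates of the dropout hazard model (see
#'   [fit_censoring_model()]); `NULL` for the default set.
#' @param stabilize Use stabilized censoring weights (marginal numerator).
#' @param score_tol,max_iter Passed to [gamma_score_solve()].
#' @return A list of class `sncstm_control`.
#' @export
sncstm_control <- function(delta = NULL, m = NULL, max_fraction = 0.10,
                           fallback_m = 20L, propensity_family = NULL,
                           history = c("full", "current"), ipcw = FALSE,
                           censoring_covariates = NULL, stabilize = FALSE,
                           score_tol = 1e-10, max_iter = 100L) {
  structure(
    list(delta = delta, m = m, max_fraction = max_fraction,
         fallback_m = fallback_m, propensity_family = propensity_family,
         history = match.arg(history), ipcw = ipcw,
         censoring_covariates = censoring_covariates, stabilize = stabilize,
         score_tol = score_tol, max_iter = max_iter),
    class = "sncstm_control"
  )
}

# propensity design column names for exposure k under a history rule
history_columns <- function(k, cov_names, history) {
  if (history == "full") {
    a_cols <- if (k > 0) paste0("A_", 0:(k - 1L)) else character(0)
    l_cols <- as.vector(outer(cov_names, 0:k, paste, sep = "_"))
  } else {
    a_cols <- if (k > 0) paste0("A_", k - 1L) else character(0)
    l_cols <- paste0(cov_names, "_", k)
  }
  c(a_cols, l_cols)
}

#' Fit the propensity model for one (exposure, window) pair
#'
#' Fits the canonical GLM for the exposure `A_k` on the pseudo rows of window
#' `l` (`l >= k`). The design contains: an intercept; the history covariates
#' at visit `k`; the elapsed-time covariate `Q - s_k` (the additive-hazard
#' structure implies the conditional exposure law among survivors shifts its
#' canonical intercept linearly in time); modifier-by-elapsed-time columns
#' when the blip specification carries effect modifiers; and, when visit
#' times vary between subjects and `l > k`, the intermediate interval-length
#' covariates `s_{j+1} - s_j`, `j = k..l-1`. Rows are weighted by the working
#' weight (censoring weights, if any) times the cumulative blip weight
#' `exp{sum_{j=k+1}^{l} H_j(Q)}` evaluated at the lower-lag estimates
#' `psi_prior`. Exposure residuals are attached for the score step.
#'
#' @param pseudo A [expand_cohort()] table.
#' @param k Exposure index.
#' @param l Window index (`k <= l`).
#' @param psi_prior Named vector of blip estimates of lag `< l - k`.
#' @param spec The [blip_spec()].
#' @param control An [sncstm_control()].
#' @return List with the `canonical_glm` fit, the window row indices,
#'   residuals, working weights, and `(k, l)`; or a list with
#'   `inestimable = TRUE` when the window holds no rows.
#' @export
fit_propensity_window <- function(pseudo, k, l, psi_prior = numeric(0),
                                  spec, control = sncstm_control()) {
  stopifnot(l >= k)
  cov_names <- attr(pseudo, "covariate_names")
  idx <- which(pseudo$visit_index == l)
  if (!length(idx)) {
    return(list(inestimable = TRUE, k = k, l = l,
                reason = "no pseudo rows in window"))
  }
  rows <- pseudo[idx, , drop = FALSE]
  a <- rows[[paste0("A_", k)]]
  fam <- control$propensity_family
  if (is.null(fam)) fam <- if (all(a %in% c(0, 1))) "binomial" else "gaussian"

  X <- cbind(`(Intercept)` = rep(1, nrow(rows)))
  for (cn in history_columns(k, cov_names, control$history)) {
    X <- cbind(X, rows[[cn]])
    colnames(X)[ncol(X)] <- cn
  }
  tshift <- rows$Q - rows[[paste0("s_", k)]]
  X <- cbind(X, Q_shift = tshift)
  for (mod in spec$modifiers) {
    X <- cbind(X, rows[[paste0(mod, "_", k)]] * tshift)
    colnames(X)[ncol(X)] <- paste0(mod, "_x_Q_shift")
  }
  if (l > k) {
    for (j in k:(l - 1L)) {
      gap <- rows[[paste0("s_", j + 1L)]] - rows[[paste0("s_", j)]]
      if (length(gap) > 1L && stats::sd(gap) > 1e-10) {
        X <- cbind(X, gap)
        colnames(X)[ncol(X)] <- paste0("gap_", j, "_", j + 1L)
      }
    }
  }
  w <- rows$work_weight * exp(blip_log_weight_rows(rows, psi_prior, spec, k, l))
  fit <- fit_canonical_glm(X, a, weights = w, family = fam)
  list(fit = fit, rows = idx, residuals = a - fit$fitted, weights = w,
       k = k, l = l, family = fam, inestimable = FALSE)
}

#' Estimate all blip parameters of one lag
#'
#' For every visit pair `(k, l = k + d)` the propensity model is fitted on
#' the window-`l` rows, blip covariates `-residual * delta_row` (and
#' `-modifier * residual * delta_row` per modifier) are formed, outcomes are
#' blipped down with the lower-lag estimates, and rows are stacked across all
#' pairs whose parameters are shared before solving one gamma score equation
#' per connected block of shared ids.
#'
#' @param pseudo A [expand_cohort()] table.
#' @param d Lag (`l - k`), non-negative.
#' @param psi_prior Named vector containing every estimate of lag `< d`.
#' @param spec The [blip_spec()].
#' @param control An [sncstm_control()].
#' @return List with `psi` (named estimates for this lag, `NA` where
#'   inestimable), `details` (per-pair diagnostics) and `propensity` (the
#'   per-pair propensity fits).
#' @export
estimate_lag <- function(pseudo, d, psi_prior = numeric(0), spec,
                         control = sncstm_control()) {
  K <- spec$K
  stopifnot(d >= 0, d <= K)
  pairs <- lapply(0:(K - d), function(k) c(k = k, l = k + d))
  pt <- spec$params[spec$params$lag == d, , drop = FALSE]
  lag_ids <- unique(pt$id)

  # per-pair propensity fits and score ingredients
  work <- vector("list", length(pairs))
  for (pi in seq_along(pairs)) {
    k <- pairs[[pi]]["k"]; l <- pairs[[pi]]["l"]
    ids <- pt$id[pt$k == k & pt$l == l]
    pf <- fit_propensity_window(pseudo, k, l, psi_prior, spec, control)
    if (isTRUE(pf$inestimable)) {
      work[[pi]] <- list(k = k, l = l, ids = ids, empty = TRUE, pf = pf)
      next
    }
    rows <- pseudo[pf$rows, , drop = FALSE]
    usable <- rows$outcome_known & rows$delta_row > 0
    if (!any(usable)) {
      work[[pi]] <- list(k = k, l = l, ids = ids, empty = TRUE, pf = pf)
      next
    }
    g <- rows[usable, , drop = FALSE]
    res <- pf$residuals[usable]
    wts <- pf$weights[usable]
    zcols <- lapply(spec$basis, function(b) {
      phi <- if (b == "1") 1 else g[[paste0(b, "_", k)]]
      -phi * res * g$delta_row
    })
    Z <- do.call(cbind, zcols)
    colnames(Z) <- vapply(spec$basis, function(b) param_id(spec, k, l, b), "")
    y <- blip_outcome_rows(g, psi_prior, spec, k, l)
    work[[pi]] <- list(k = k, l = l, ids = ids, empty = FALSE,
                       Z = Z, y = y, w = wts, n = nrow(g), pf = pf)
  }

  # connected blocks of pairs through shared parameter ids
  blocks <- list()
  assigned <- rep(FALSE, length(work))
  for (pi in seq_along(work)) {
    if (assigned[pi]) next
    members <- pi
    repeat {
      ids_in <- unique(unlist(lapply(work[members], `[[`, "ids")))
      more <- which(!assigned & vapply(work, function(wk) {
        any(wk$ids %in% ids_in)
      }, logical(1)))
      more <- setdiff(more, members)
      if (!length(more)) break
      members <- c(members, more)
    }
    assigned[members] <- TRUE
    blocks[[length(blocks) + 1L]] <- members
  }

  psi <- stats::setNames(rep(NA_real_, length(lag_ids)), lag_ids)
  details <- list()
  for (bl in blocks) {
    parts <- work[bl]
    live <- parts[!vapply(parts, `[[`, logical(1), "empty")]
    ids_b <- unique(unlist(lapply(parts, `[[`, "ids")))
    if (!length(live)) {
      details[[length(details) + 1L]] <- list(
        pairs = lapply(parts, function(z) c(z$k, z$l)),
        ids = ids_b, inestimable = TRUE, n = 0L)
      next
    }
    n_tot <- sum(vapply(live, `[[`, integer(1), "n"))
    ids_live <- unique(unlist(lapply(live, function(z) colnames(z$Z))))
    Zb <- matrix(0, n_tot, length(ids_live), dimnames = list(NULL, ids_live))
    yb <- numeric(n_tot); wb <- numeric(n_tot)
    at <- 0L
    for (z in live) {
      rng <- at + seq_len(z$n)
      Zb[rng, colnames(z$Z)] <- z$Z
      yb[rng] <- z$y
      wb[rng] <- z$w
      at <- at + z$n
    }
    sol <- gamma_score_solve(Zb, yb, wb, tol = control$score_tol,
                             max_iter = control$max_iter)
    psi[ids_live] <- sol$coefficients[ids_live]
    details[[length(details) + 1L]] <- list(
      pairs = lapply(parts, function(z) c(z$k, z$l)),
      ids = ids_b, inestimable = FALSE, n = n_tot,
      score_norm = sol$score_norm, iterations = sol$iterations)
  }
  list(psi = psi, details = details,
       propensity = lapply(work, function(z) z$pf))
}

#' Fit a Structural Nested Cumulative Survival Time Model by g-estimation
#'
#' Runs the full pipeline: grid-step selection (unless fixed), expansion into
#' pseudo-individuals, optional censoring model and inverse probability of
#' censoring weights, then sequential estimation of the blip parameters by
#' ascending lag `d = l - k`. The ordering is what makes the procedure
#' non-iterative: the weights and blipped outcomes needed at lag `d` involve
#' only parameters of lag `< d`.
#'
#' @param cohort An [sncstm_cohort()]; it is validated first and any
#'   violation is fatal unless `validate = FALSE`.
#' @param spec A [blip_spec()]; defaults to no effect modification, no
#'   sharing, with `K` taken from the cohort's longest visit schedule.
#' @param control An [sncstm_control()].
#' @param validate Set `FALSE` to skip the data contract check.
#' @return Object of class `sncstm_fit`: `psi` (named estimates, `NA` +
#'   `inestimable` flag for empty windows), `delta`, the censoring model (if
#'   any), per-lag diagnostics, propensity fits, and accumulated warnings.
#' @export
fit_sncstm <- function(cohort, spec = NULL, control = sncstm_control(),
                       validate = TRUE) {
  stopifnot(inherits(cohort, "sncstm_cohort"))
  if (validate) {
    bad <- validate_cohort(cohort)
    if (length(bad)) {
      stop("cohort fails validation:\n  ", paste(bad, collapse = "\n  "))
    }
  }
  if (is.null(spec)) {
    K <- max(vapply(cohort$records, function(r) length(r$visit_times), integer(1))) - 1L
    spec <- blip_spec(K)
  }
  warns <- character(0)
  delta <- control$delta
  if (is.null(delta)) {
    delta <- withCallingHandlers(
      choose_delta(cohort, control$max_fraction, control$fallback_m,
                   m = control$m),
      warning = function(w) {
        warns <<- c(warns, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
  }
  pseudo <- expand_cohort(cohort, delta)
  cens <- NULL
  if (isTRUE(control$ipcw)) {
    cens <- fit_censoring_model(pseudo, covariates = control$censoring_covariates)
    if (!is.null(cens$note)) warns <- c(warns, cens$note)
    pseudo <- ipcw_weights(cens, pseudo, stabilize = control$stabilize)
  }
  psi <- numeric(0)
  diagnostics <- list()
  propensity <- list()
  for (d in 0:spec$K) {
    lr <- estimate_lag(pseudo, d, psi_prior = psi, spec = spec,
                       control = control)
    psi <- c(psi, lr$psi)
    diagnostics[[paste0("lag", d)]] <- lr$details
    propensity <- c(propensity, lr$propensity)
  }
  inest <- names(psi)[is.na(psi)]
  if (length(inest)) {
    warns <- c(warns, paste0("inestimable parameter(s): ",
                             paste(inest, collapse = ", ")))
  }
  structure(
    list(psi = psi[spec$parameter_ids], delta = delta, spec = spec,
         control = control, censoring_model = cens,
         diagnostics = diagnostics, propensity = propensity,
         n_subjects = length(cohort$records),
         n_pseudo = nrow(pseudo), warnings = warns,
         boot = NULL, call = match.call()),
    class = "sncstm_fit"
  )
}

#' @export
coef.sncstm_fit <- function(object, ...) object$psi

#' @export
print.sncstm_fit <- function(x, ...) {
  cat("SNCSTM g-estimation fit\n")
  cat("  subjects:", x$n_subjects, "  pseudo-individuals:", x$n_pseudo,
      "  delta:", signif(x$delta, 6), "\n")
  est <- data.frame(estimate = signif(x$psi, 6))
  if (!is.null(x$boot)) {
    est$se <- signif(x$boot$se[rownames(est)], 4)
    est$ci_lo <- signif(x$boot$ci[rownames(est), 1L], 4)
    est$ci_hi <- signif(x$boot$ci[rownames(est), 2L], 4)
  }
  print(est)
  if (length(x$warnings)) {
    cat("Warnings:\n")
    for (w in x$warnings) cat("  -", w, "\n")
  }
  invisible(x)
}
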