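#' Fit a discrete-time dropout (censoring) hazard model
#'
#' Pools the pseudo rows over all grid intervals and fits a binomial-logit
#' model for the event "dropout in `(Q, Q + delta_row]`" on history covariates
#' measured at the row's current visit plus the grid time `Q`. Dropout means
#' censoring strictly before the subject's administrative end; administrative
#' censoring is never modelled as dropout. Rows after a subject's dropout do
#' not exist in the expansion, so every row is at risk.
#'
#' @param pseudo A [expand_cohort()] table.
#' @param covariates Character vector of column-name stems: each confounder
#'   name and/or `"A"` (current exposure) and/or `"Q"`. Default: all
#'   confounders at the current visit, the current exposure, and `Q`.
#' @return Object of class `censoring_model`: the `canonical_glm` fit (or
#'   `NULL` for the trivial no-dropout model), the fitted per-row hazards,
#'   the covariate set and a `note` when the model is trivial.
#' @export
fit_censoring_model <- function(pseudo, covariates = NULL) {
  cov_names <- attr(pseudo, "covariate_names")
  if (is.null(covariates)) covariates <- c(cov_names, "A", "Q")
  dropout_subject <- pseudo$event == 0L & pseudo$T < pseudo$admin_end
  d <- as.integer(dropout_subject &
                    pseudo$T > pseudo$Q &
                    pseudo$T <= pseudo$Q + pseudo$delta_row)
  if (!any(d == 1L)) {
    return(structure(
      list(fit = NULL, hazards = rep(0, nrow(pseudo)),
           covariates = covariates,
           note = "no dropout events; trivial censoring model (hazard 0)"),
      class = "censoring_model"
    ))
  }
  X <- cbind(`(Intercept)` = rep(1, nrow(pseudo)))
  k <- pseudo$visit_index
  for (cn in covariates) {
    if (cn == "Q") {
      X <- cbind(X, Q = pseudo$Q)
    } else {
      stem <- if (cn == "A") "A_" else paste0(cn, "_")
      val <- numeric(nrow(pseudo))
      for (kk in unique(k)) {
        sel <- k == kk
        val[sel] <- pseudo[[paste0(stem, kk)]][sel]
      }
      X <- cbind(X, val)
      colnames(X)[ncol(X)] <- if (cn == "A") "A_current" else paste0(cn, "_current")
    }
  }
  fit <- fit_canonical_glm(X, d, family = "binomial")
  structure(
    list(fit = fit, hazards = fit$fitted, covariates = covariates,
         note = NULL),
    class = "censoring_model"
  )
}

#' @export
print.censoring_model <- function(x, ...) {
  if (is.null(x$fit)) {
    cat("Trivial censoring model (no dropout events; hazard 0)\n")
  } else {
    cat("Discrete-time dropout hazard model (pooled logistic)\n")
    print(signif(x$fit$coefficients, 6))
  }
  invisible(x)
}

#' Apply inverse probability of censoring weights to a pseudo table
#'
#' Each row's working weight is multiplied by one over the estimated
#' probability of remaining uncensored at its grid time: the product of
#' `1 - hazard` over the subject's own earlier grid intervals (those with
#' `Q' < Q`). Multipliers are therefore at least 1 and non-decreasing in `Q`
#' within a subject. With stabilization, the numerator is the same product
#' under an intercept-only (marginal) hazard model. Rows whose survival
#' status at `Q + delta_row` is unobserved keep `outcome_known = FALSE` and
#' remain excluded from the gamma score fits.
#'
#' @param model A [fit_censoring_model()] object fitted on the same table.
#' @param pseudo The [expand_cohort()] table.
#' @param stabilize Multiply by the marginal uncensored probability.
#' @return The pseudo table with updated `work_weight`.
#' @export
ipcw_weights <- function(model, pseudo, stabilize = FALSE) {
  stopifnot(inherits(model, "censoring_model"))
  h <- model$hazards
  if (length(h) != nrow(pseudo)) {
    stop("censoring model was not fitted on this pseudo table")
  }
  if (any(h >= 1 - 1e-12)) {
    stop("predicted censoring hazard numerically 1; weights would explode")
  }
  # rows are ordered by (subject, Q); lagged cumulative sum of log(1 - h)
  ord <- order(pseudo$subject_id, pseudo$Q)
  if (any(ord != seq_along(ord))) {
    pseudo <- pseudo[ord, , drop = FALSE]
    h <- h[ord]
  }
  sid <- pseudo$subject_id
  cum <- stats::ave(log1p(-h), sid,
                    FUN = function(z) cumsum(c(0, z[-length(z)])))
  mult <- exp(-cum)
  if (stabilize) {
    h0 <- rep(model_hazard_mean(model, pseudo), nrow(pseudo))
    cum0 <- stats::ave(log1p(-h0), sid,
                       FUN = function(z) cumsum(c(0, z[-length(z)])))
    mult <- mult * exp(cum0)
  }
  pseudo$work_weight <- pseudo$work_weight * mult
  pseudo
}

# marginal per-interval dropout hazard (intercept-only pooled model)
model_hazard_mean <- function(model, pseudo) {
  if (is.null(model$fit)) return(0)
  dropout_subject <- pseudo$event == 0L & pseudo$T < pseudo$admin_end
  d <- as.integer(dropout_subject &
                    pseudo$T > pseudo$Q &
                    pseudo$T <= pseudo$Q + pseudo$delta_row)
  mean(d)
}
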