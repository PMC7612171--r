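#' Bootstrap standard errors and percentile intervals for an SNCSTM fit
#'
#' Resamples subjects with replacement `B` times and refits the entire
#' pipeline per replicate: propensity models, censoring model and weights,
#' and all blip score equations. The grid step is held at the original fit's
#' `delta` so that every replicate is estimated on the same discretization.
#' Replicates that fail to converge (or hit a degenerate window) are dropped
#' and counted; more than 20% failures attaches a warning.
#'
#' @param cohort The original [sncstm_cohort()].
#' @param fit The [fit_sncstm()] result to attach intervals to.
#' @param B Number of bootstrap replicates (`B = 0` returns the fit with
#'   empty standard-error slots).
#' @param seed Integer seed; the same seed reproduces the intervals exactly.
#' @return The fit with a `boot` element: `se` (empirical SDs), `ci`
#'   (2.5/97.5 percentile matrix), `B`, `n_failed`, `warnings`.
#' @export
bootstrap_sncstm <- function(cohort, fit, B, seed = NULL) {
  stopifnot(inherits(cohort, "sncstm_cohort"), inherits(fit, "sncstm_fit"),
            B >= 0)
  if (B == 0) {
    fit$boot <- list(se = NULL, ci = NULL, B = 0L, n_failed = 0L,
                     warnings = character(0))
    return(fit)
  }
  if (!is.null(seed)) set.seed(seed)
  control <- fit$control
  control$delta <- fit$delta
  n <- length(cohort$records)
  ids <- fit$spec$parameter_ids
  draws <- matrix(NA_real_, B, length(ids), dimnames = list(NULL, ids))
  n_failed <- 0L
  for (b in seq_len(B)) {
    take <- sample.int(n, n, replace = TRUE)
    recs <- cohort$records[take]
    for (i in seq_along(recs)) recs[[i]]$subject_id <- as.character(i)
    boot_cohort <- sncstm_cohort(recs, cohort$covariate_names)
    est <- tryCatch(
      suppressWarnings(
        fit_sncstm(boot_cohort, spec = fit$spec, control = control,
                   validate = FALSE)$psi
      ),
      error = function(e) NULL
    )
    if (is.null(est) || anyNA(est)) {
      n_failed <- n_failed + 1L
    } else {
      draws[b, ] <- est[ids]
    }
  }
  ok <- stats::complete.cases(draws)
  warns <- character(0)
  if (n_failed > 0.2 * B) {
    warns <- paste0("bootstrap: ", n_failed, " of ", B,
                    " replicates failed to converge")
  }
  good <- draws[ok, , drop = FALSE]
  fit$boot <- list(
    se = apply(good, 2L, stats::sd),
    ci = t(apply(good, 2L, stats::quantile, probs = c(0.025, 0.975),
                 na.rm = TRUE)),
    B = B, n_failed = n_failed, warnings = warns
  )
  if (length(warns)) fit$warnings <- c(fit$warnings, warns)
  fit
}
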