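#' Read a cohort from subjects and visits CSV files
#'
#' The subjects file must have columns `subject_id`, `followup_time`,
#' `event`, `admin_end` (one row per subject); the visits file must have
#' `subject_id`, `visit_index`, `visit_time`, `exposure`, followed by one
#' column per confounder. Visits attended after a subject's end of follow-up
#' are expected to be absent (or have `NA` exposure/confounders).
#'
#' @param subjects_path,visits_path Paths to the two CSV files.
#' @param validate Fail on any data-contract violation (default).
#' @return An [sncstm_cohort()].
#' @export
read_cohort <- function(subjects_path, visits_path, validate = TRUE) {
  subjects <- utils::read.csv(subjects_path, stringsAsFactors = FALSE)
  visits <- utils::read.csv(visits_path, stringsAsFactors = FALSE)
  need_s <- c("subject_id", "followup_time", "event", "admin_end")
  need_v <- c("subject_id", "visit_index", "visit_time", "exposure")
  for (cn in need_s) {
    if (!cn %in% names(subjects)) {
      stop("subjects file is missing column `", cn, "`")
    }
  }
  for (cn in need_v) {
    if (!cn %in% names(visits)) {
      stop("visits file is missing column `", cn, "`")
    }
  }
  cov_names <- setdiff(names(visits), need_v)
  if (!length(cov_names)) stop("visits file has no confounder columns")
  subjects$subject_id <- as.character(subjects$subject_id)
  visits$subject_id <- as.character(visits$subject_id)
  unknown <- setdiff(visits$subject_id, subjects$subject_id)
  if (length(unknown)) {
    stop("visits file references unknown subject_id(s): ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  }
  records <- vector("list", nrow(subjects))
  vsplit <- split(visits, visits$subject_id)
  for (i in seq_len(nrow(subjects))) {
    si <- subjects[i, ]
    v <- vsplit[[si$subject_id]]
    if (is.null(v) || !nrow(v)) {
      stop("no visit rows for subject ", si$subject_id)
    }
    v <- v[order(v$visit_index), , drop = FALSE]
    records[[i]] <- subject_record(
      subject_id = si$subject_id,
      visit_times = v$visit_time,
      exposures = v$exposure,
      confounders = as.matrix(v[, cov_names, drop = FALSE]),
      followup_time = si$followup_time,
      event = si$event,
      admin_end = si$admin_end
    )
  }
  cohort <- sncstm_cohort(records, cov_names)
  if (validate) {
    bad <- validate_cohort(cohort)
    if (length(bad)) {
      stop("cohort fails validation:\n  ", paste(bad, collapse = "\n  "))
    }
  }
  cohort
}

#' Write a cohort to subjects and visits CSV files
#'
#' Inverse of [read_cohort()]: unattended visits are written with `NA`
#' exposure and confounders so that the visit schedule round-trips.
#'
#' @param cohort An [sncstm_cohort()].
#' @param subjects_path,visits_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_cohort <- function(cohort, subjects_path, visits_path) {
  stopifnot(inherits(cohort, "sncstm_cohort"))
  subjects <- do.call(rbind, lapply(cohort$records, function(r) {
    data.frame(subject_id = r$subject_id, followup_time = r$followup_time,
               event = r$event, admin_end = r$admin_end,
               stringsAsFactors = FALSE)
  }))
  visits <- do.call(rbind, lapply(cohort$records, function(r) {
    d <- data.frame(subject_id = r$subject_id,
                    visit_index = seq_along(r$visit_times) - 1L,
                    visit_time = r$visit_times,
                    exposure = r$exposures,
                    stringsAsFactors = FALSE)
    cbind(d, as.data.frame(r$confounders))
  }))
  utils::write.csv(subjects, subjects_path, row.names = FALSE)
  utils::write.csv(visits, visits_path, row.names = FALSE)
  invisible(c(subjects_path, visits_path))
}

#' Serialize a fit to JSON
#'
#' Writes the grid step, one entry per `(k, l, basis)` triple (with its
#' shared parameter id, estimate, optional bootstrap SE and percentile CI,
#' and an `inestimable` flag), accumulated warnings, and compact propensity
#' model summaries. Floats are written at full precision.
#'
#' @param fit An [fit_sncstm()] result.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "sncstm_fit"))
  pt <- fit$spec$params
  params <- lapply(seq_len(nrow(pt)), function(i) {
    id <- pt$id[i]
    est <- unname(fit$psi[id])
    out <- list(id = id, k = pt$k[i], l = pt$l[i], basis = pt$basis[i],
                estimate = if (is.na(est)) NULL else est,
                inestimable = is.na(est))
    if (!is.null(fit$boot) && !is.null(fit$boot$se) && !is.na(est)) {
      out$se <- unname(fit$boot$se[id])
      out$ci <- unname(fit$boot$ci[id, ])
    }
    out
  })
  prop <- lapply(Filter(function(p) !isTRUE(p$inestimable), fit$propensity),
                 function(p) {
                   list(k = p$k, l = p$l, family = p$family,
                        coefficients = as.list(p$fit$coefficients))
                 })
  obj <- list(delta = fit$delta, parameters = params,
              warnings = fit$warnings, propensity = prop)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read back a serialized fit
#'
#' Parses a [write_fit()] JSON file; returns the parameter map and metadata
#' (not a full refittable object).
#'
#' @param path Path to the JSON file.
#' @return List with `delta`, `psi` (named vector, `NA` for inestimable
#'   parameters), `parameters` (full table), `warnings`.
#' @export
read_fit <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  ids <- vapply(obj$parameters, `[[`, "", "id")
  est <- vapply(obj$parameters, function(p) {
    if (isTRUE(p$inestimable) || is.null(p$estimate)) NA_real_
    else as.numeric(p$estimate)
  }, numeric(1))
  psi <- stats::setNames(est, ids)
  psi <- psi[!duplicated(ids)]
  list(delta = obj$delta, psi = psi, parameters = obj$parameters,
       warnings = unlist(obj$warnings))
}
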