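#' Construct a single subject record
#'
#' A subject record holds the full longitudinal history of one individual:
#' the scheduled visit times `s_0 < s_1 < ... < s_K` (with `s_0 = 0`), the
#' exposure `A_k` and confounder vector `L_k` measured at each attended visit,
#' the follow-up time `T` (the minimum of the failure and censoring times),
#' the event indicator, and the administrative end of follow-up `C`.
#'
#' Exposures and confounders are recorded as `NA` for visits the subject did
#' not attend, i.e. visits with `s_k > T`. A death occurring exactly at a
#' visit time contributes no exposure at that visit: exposure cannot act over
#' zero elapsed time, so it is treated as unmeasured there.
#'
#' @param subject_id Scalar identifier (coerced to character).
#' @param visit_times Numeric vector of strictly increasing visit times,
#'   starting at 0.
#' @param exposures Numeric vector, one entry per visit (`NA` after end of
#'   follow-up). Binary exposures are coded 0/1.
#' @param confounders Numeric matrix with one row per visit and one column per
#'   confounder (a vector is treated as a single-confounder matrix).
#' @param followup_time Non-negative follow-up time `T`.
#' @param event 1 if failure was observed at `followup_time`, 0 if censored.
#' @param admin_end Administrative censoring time `C > 0`.
#'
#' @return An object of class `subject_record`.
#' @seealso [sncstm_cohort()], [validate_cohort()]
#' @export
subject_record <- function(subject_id, visit_times, exposures, confounders,
                           followup_time, event, admin_end) {
  if (is.null(dim(confounders))) {
    confounders <- matrix(confounders, ncol = 1L)
  }
  confounders <- as.matrix(confounders)
  rownames(confounders) <- NULL
  if (nrow(confounders) != length(visit_times) ||
      length(exposures) != length(visit_times)) {
    stop("exposures and confounders must have one entry/row per visit time")
  }
  structure(
    list(
      subject_id    = as.character(subject_id)[1L],
      visit_times   = as.numeric(visit_times),
      exposures     = as.numeric(exposures),
      confounders   = confounders,
      followup_time = as.numeric(followup_time)[1L],
      event         = as.integer(event)[1L],
      admin_end     = as.numeric(admin_end)[1L]
    ),
    class = "subject_record"
  )
}

#' Assemble a cohort from subject records
#'
#' @param records List of [subject_record()] objects.
#' @param covariate_names Character vector naming the confounder columns. If
#'   `NULL`, names are taken from the first record's confounder matrix, or
#'   generated as `L1, L2, ...`.
#'
#' @return An object of class `sncstm_cohort` with elements `records` and
#'   `covariate_names`.
#' @export
sncstm_cohort <- function(records, covariate_names = NULL) {
  if (!length(records)) stop("cohort must contain at least one record")
  if (!all(vapply(records, inherits, logical(1), "subject_record"))) {
    stop("all elements of `records` must be subject_record objects")
  }
  p <- ncol(records[[1L]]$confounders)
  if (is.null(covariate_names)) {
    covariate_names <- colnames(records[[1L]]$confounders)
    if (is.null(covariate_names)) covariate_names <- paste0("L", seq_len(p))
  }
  if (length(covariate_names) != p) {
    stop("covariate_names must match the confounder dimension")
  }
  records <- lapply(records, function(r) {
    colnames(r$confounders) <- covariate_names
    r
  })
  structure(
    list(records = records, covariate_names = covariate_names),
    class = "sncstm_cohort"
  )
}

#' @export
print.sncstm_cohort <- function(x, ...) {
  n <- length(x$records)
  nv <- vapply(x$records, function(r) length(r$visit_times), integer(1))
  ev <- sum(vapply(x$records, function(r) r$event, integer(1)))
  cat("SNCSTM cohort:", n, "subjects,",
      if (min(nv) == max(nv)) paste(max(nv), "visits each")
      else paste0(min(nv), "-", max(nv), " visits"),
      "\n")
  cat("  confounders:", paste(x$covariate_names, collapse = ", "), "\n")
  cat("  observed failures:", ev,
      sprintf("(%.1f%%)", 100 * ev / n), "\n")
  invisible(x)
}

#' @export
length.sncstm_cohort <- function(x) length(x$records)

# Is the visit attended (exposure measurable)? T >= s_k, except a failure
# occurring exactly at s_k, which contributes no exposure.
visit_attended <- function(record, k) {
  s_k <- record$visit_times[k + 1L]
  record$followup_time >= s_k &&
    !(record$event == 1L && record$followup_time == s_k)
}

#' Validate a cohort against the SNCSTM data contract
#'
#' Checks every record for: strictly increasing visit times starting at 0 with
#' the last visit before `admin_end`; `followup_time` within `[0, admin_end]`;
#' no observed event exactly at the administrative end (an administrative
#' censoring time by definition yields `event = 0`); exposure/confounder
#' presence exactly at attended visits; no partially missing confounder
#' vectors at attended visits; unique subject ids; and a common confounder
#' dimension. Validation reports, it never raises.
#'
#' @param cohort An [sncstm_cohort()].
#' @return Character vector of violation messages, each naming the subject and
#'   the broken rule; `character(0)` if the cohort is well formed.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "sncstm_cohort"))
  out <- character(0)
  p <- length(cohort$covariate_names)
  ids <- vapply(cohort$records, function(r) r$subject_id, character(1))
  if (anyDuplicated(ids)) {
    out <- c(out, paste0("duplicated subject_id: ",
                         paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  for (r in cohort$records) {
    id <- r$subject_id
    s <- r$visit_times
    K <- length(s) - 1L
    if (ncol(r$confounders) != p) {
      out <- c(out, paste0("subject ", id, ": confounder dimension ",
                           ncol(r$confounders), " != ", p))
      next
    }
    if (s[1L] != 0) {
      out <- c(out, paste0("subject ", id, ": first visit time must be 0"))
    }
    if (K >= 1L && any(diff(s) <= 0)) {
      out <- c(out, paste0("subject ", id, ": visit times not strictly increasing"))
    }
    if (!is.finite(r$admin_end) || r$admin_end <= 0) {
      out <- c(out, paste0("subject ", id, ": admin_end must be positive"))
    }
    if (s[K + 1L] >= r$admin_end) {
      out <- c(out, paste0("subject ", id, ": last visit time not before admin_end"))
    }
    if (!is.finite(r$followup_time) || r$followup_time < 0) {
      out <- c(out, paste0("subject ", id, ": followup_time must be non-negative"))
    }
    if (r$followup_time > r$admin_end) {
      out <- c(out, paste0("subject ", id, ": followup_time exceeds admin_end"))
    }
    if (r$event == 1L && r$followup_time == r$admin_end) {
      out <- c(out, paste0("subject ", id,
                           ": event recorded at admin_end (administrative censoring rule)"))
    }
    for (k in 0:K) {
      attended <- visit_attended(r, k)
      a_there <- !is.na(r$exposures[k + 1L])
      l_there <- !anyNA(r$confounders[k + 1L, ])
      if (attended && !a_there) {
        out <- c(out, paste0("subject ", id, ": exposure missing at attended visit ", k))
      }
      if (attended && !l_there) {
        out <- c(out, paste0("subject ", id, ": confounder missing at attended visit ", k))
      }
      if (!attended && a_there) {
        out <- c(out, paste0("subject ", id,
                             ": exposure recorded at visit ", k,
                             " after end of follow-up"))
      }
      if (!attended && l_there) {
        out <- c(out, paste0("subject ", id,
                             ": confounder recorded at visit ", k,
                             " after end of follow-up"))
      }
    }
  }
  out
}

# Padded-array view of a cohort used by the expansion and the simulator-facing
# diagnostics: n x (Kmax+1) matrices of visit times, exposures and each
# confounder, plus per-subject scalars. NA marks unattended visits.
cohort_arrays <- function(cohort) {
  recs <- cohort$records
  n <- length(recs)
  nv <- vapply(recs, function(r) length(r$visit_times), integer(1))
  Kmax <- max(nv) - 1L
  p <- length(cohort$covariate_names)
  S <- A <- matrix(NA_real_, n, Kmax + 1L)
  L <- lapply(seq_len(p), function(j) matrix(NA_real_, n, Kmax + 1L))
  for (i in seq_len(n)) {
    r <- recs[[i]]
    k <- seq_len(nv[i])
    S[i, k] <- r$visit_times
    A[i, k] <- r$exposures
    for (j in seq_len(p)) L[[j]][i, k] <- r$confounders[, j]
  }
  names(L) <- cohort$covariate_names
  list(
    n = n, Kmax = Kmax, n_visits = nv,
    S = S, A = A, L = L,
    subject_id = vapply(recs, function(r) r$subject_id, character(1)),
    T = vapply(recs, function(r) r$followup_time, numeric(1)),
    event = vapply(recs, function(r) r$event, integer(1)),
    C = vapply(recs, function(r) r$admin_end, numeric(1))
  )
}
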