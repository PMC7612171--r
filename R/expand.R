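#' Choose the grid step for the pseudo-individual expansion
#'
#' The estimator discretises follow-up into intervals of length `delta`. The
#' step should be small enough that no single interval carries a substantial
#' share of the observed failures: within every inter-visit window
#' `[s_l, s_{l+1}]` (and the terminal window up to the administrative end), no
#' one sub-interval may contain more than `max_fraction` of the failures
#' observed in that window. Candidate steps are of the form
#' (largest window length) / m for integer m; the largest admissible step is
#' returned. When the rule cannot be satisfied (e.g. a window with fewer than
#' `1 / max_fraction` failures, where a single failure already exceeds the
#' share), the fallback (smallest window length) / `fallback_m` is returned
#' with a warning; for a single window of length `C` this is the conventional
#' `C / 20`.
#'
#' Windows are taken from a reference schedule: the visit times of the first
#' record together with the largest administrative end in the cohort.
#'
#' @param cohort An [sncstm_cohort()].
#' @param max_fraction Largest admissible share of a window's failures in one
#'   sub-interval (default 0.10).
#' @param fallback_m Number of sub-intervals used by the fallback rule.
#' @param m Optional integer: bypass the search and return
#'   (smallest window length) / `m` directly.
#' @return The chosen step `delta` (scalar).
#' @export
choose_delta <- function(cohort, max_fraction = 0.10, fallback_m = 20L,
                         m = NULL) {
  stopifnot(inherits(cohort, "sncstm_cohort"), max_fraction > 0)
  s_ref <- cohort$records[[1L]]$visit_times
  C <- max(vapply(cohort$records, function(r) r$admin_end, numeric(1)))
  bounds <- c(s_ref, C)
  lens <- diff(bounds)
  if (any(lens <= 0)) stop("degenerate reference schedule")
  if (!is.null(m)) return(min(lens) / as.integer(m))

  Tf <- vapply(cohort$records, function(r) r$followup_time, numeric(1))
  evt <- vapply(cohort$records, function(r) r$event, integer(1)) == 1L
  fail <- Tf[evt]
  n_win <- length(lens)
  # failures per window, [a, b) half-open
  win_fail <- lapply(seq_len(n_win), function(w) {
    fail[fail >= bounds[w] & fail < bounds[w + 1L]]
  })
  counts <- lengths(win_fail)
  fallback <- function(msg) {
    warning("choose_delta: ", msg, "; falling back to delta = ",
            signif(min(lens) / fallback_m, 6), call. = FALSE)
    min(lens) / fallback_m
  }
  if (!length(fail)) return(fallback("no observed failures"))
  if (any(counts > 0 & counts < 1 / max_fraction)) {
    return(fallback("a window has too few failures for the share rule"))
  }
  L_ref <- max(lens)
  for (mm in seq_len(500L)) {
    delta <- L_ref / mm
    if (delta >= min(lens)) next   # grid would skip the narrowest window
    ok <- TRUE
    for (w in seq_len(n_win)) {
      if (!counts[w]) next
      j <- floor((win_fail[[w]] - bounds[w]) / delta)
      if (max(tabulate(j + 1L)) > max_fraction * counts[w]) { ok <- FALSE; break }
    }
    if (ok) return(delta)
  }
  fallback("no admissible delta up to m = 500")
}

#' Expand a cohort into pseudo-individuals on a delta-grid
#'
#' For each subject and each attended visit `k`, rows are emitted at grid
#' times `Q = s_k, s_k + delta, s_k + 2*delta, ...` up to the smaller of the
#' next visit time, the follow-up time and the administrative end. The grid is
#' re-anchored at each visit, so visit times need not be multiples of `delta`;
#' a short final sub-interval before the next visit is emitted with its actual
#' length `delta_row < delta`, which then replaces `delta` in all blip and
#' outcome formulas for that row. A grid time falling exactly on the next
#' visit is attributed to the later window (where it is that window's anchor).
#'
#' Each row carries the survival outcome `surv_next = I(T >= Q + delta_row)`
#' over the half-open interval `[Q, Q + delta_row)`; a failure exactly at
#' `Q + delta_row` counts as surviving to it. `outcome_known` is `FALSE` for
#' rows whose status at `Q + delta_row` is unobservable (the subject was
#' censored inside the interval, or the row sits exactly at the administrative
#' end with no forward interval); such rows are excluded from all gamma score
#' fits but still contribute to propensity fits.
#'
#' @param cohort An [sncstm_cohort()].
#' @param delta Grid step, `0 < delta <` the smallest inter-visit gap
#'   (including the terminal window up to the administrative end).
#' @return A `data.frame` of class `pseudo_table` with columns `subject_id`,
#'   `Q`, `delta_row`, `visit_index`, `surv_next`, `outcome_known`,
#'   `work_weight`, follow-up bookkeeping (`T`, `event`, `admin_end`), visit
#'   times `s_0 ...`, exposures `A_0 ...` and one column per confounder and
#'   visit (`<name>_0 ...`). History columns beyond the row's window are `NA`.
#' @export
expand_cohort <- function(cohort, delta) {
  stopifnot(inherits(cohort, "sncstm_cohort"), delta > 0)
  ca <- cohort_arrays(cohort)
  gaps <- apply(cbind(ca$S, ca$C), 1L, function(z) min(diff(z[!is.na(z)])))
  if (delta >= min(gaps)) {
    stop("delta (", delta, ") must be smaller than the smallest inter-visit gap (",
         min(gaps), "): the grid would skip a window")
  }
  p <- length(ca$L)
  cov_names <- names(ca$L)
  eps <- delta * 1e-9
  blocks <- vector("list", ca$Kmax + 1L)
  for (k in 0:ca$Kmax) {
    attended <- !is.na(ca$A[, k + 1L])
    idx <- which(attended)
    if (!length(idx)) next
    a <- ca$S[idx, k + 1L]
    next_s <- if (k < ca$Kmax) ca$S[idx, k + 2L] else rep(NA_real_, length(idx))
    win_end <- ifelse(is.na(next_s), ca$C[idx], next_s)
    b <- pmin(win_end, ca$T[idx])
    jmax <- floor((b - a) / delta + eps)
    rid <- rep.int(seq_along(idx), jmax + 1L)
    j <- sequence(jmax + 1L) - 1L
    Q <- a[rid] + j * delta
    # boundary rows belong to the later window when that visit is attended
    next_attended <- if (k < ca$Kmax) !is.na(ca$A[idx, k + 2L]) else rep(FALSE, length(idx))
    drop <- next_attended[rid] & !is.na(next_s[rid]) & abs(Q - next_s[rid]) < eps
    keep <- !drop
    rid <- rid[keep]; Q <- Q[keep]
    if (!length(rid)) next
    drow <- pmax(pmin(delta, win_end[rid] - Q), 0)
    Ti <- ca$T[idx][rid]
    evi <- ca$event[idx][rid]
    known <- drow > 0 & (evi == 1L | Ti >= Q + drow - eps)
    sn <- ifelse(known, as.integer(Ti >= Q + drow - eps), NA_integer_)
    bl <- data.frame(
      subject_id = ca$subject_id[idx][rid],
      Q = Q, delta_row = drow, visit_index = k,
      surv_next = sn, outcome_known = known,
      work_weight = 1,
      T = Ti, event = evi, admin_end = ca$C[idx][rid],
      stringsAsFactors = FALSE
    )
    # history snapshot: visit times, exposures, confounders up to visit k only
    for (kk in 0:ca$Kmax) {
      obs <- kk <= k
      bl[[paste0("s_", kk)]] <- if (obs) ca$S[idx, kk + 1L][rid] else NA_real_
      bl[[paste0("A_", kk)]] <- if (obs) ca$A[idx, kk + 1L][rid] else NA_real_
      for (jj in seq_len(p)) {
        bl[[paste0(cov_names[jj], "_", kk)]] <-
          if (obs) ca$L[[jj]][idx, kk + 1L][rid] else NA_real_
      }
    }
    blocks[[k + 1L]] <- bl
  }
  out <- do.call(rbind, blocks[!vapply(blocks, is.null, logical(1))])
  ord <- order(out$subject_id, out$Q)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "delta") <- delta
  attr(out, "covariate_names") <- cov_names
  attr(out, "Kmax") <- ca$Kmax
  class(out) <- c("pseudo_table", "data.frame")
  out
}
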