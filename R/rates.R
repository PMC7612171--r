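#' Crude death rates and one-period survival ratio
#'
#' Computes event rates per unit person-time in the treated and untreated
#' states and the implied ratio of one-time-unit survival probabilities under
#' constant hazards, `exp(-rate_treated) / exp(-rate_untreated)`. This is the
#' naive descriptive contrast one would quote before any confounding
#' adjustment.
#'
#' @param events_treated,events_untreated Event counts (non-negative).
#' @param py_treated,py_untreated Person-time at risk in each state (positive).
#' @return Named list with `rate_treated`, `rate_untreated` and
#'   `survival_ratio`.
#' @examples
#' crude_rates(74, 3930, 63, 8450)
#' @export
crude_rates <- function(events_treated, py_treated,
                        events_untreated, py_untreated) {
  if (py_treated <= 0 || py_untreated <= 0) {
    stop("person-time must be positive in both exposure states")
  }
  if (events_treated < 0 || events_untreated < 0) {
    stop("event counts must be non-negative")
  }
  rt <- events_treated / py_treated
  ru <- events_untreated / py_untreated
  list(
    rate_treated = rt,
    rate_untreated = ru,
    survival_ratio = exp(-rt) / exp(-ru)
  )
}

#' Classify person-time and events by current exposure status
#'
#' Splits each subject's follow-up into the inter-visit intervals
#' `[s_k, min(s_{k+1}, T))` and attributes the person-time of each interval to
#' the exposure status `A_k` held at its start. An observed failure is
#' attributed to the exposure status of the interval in which it occurs. The
#' person-time decomposition is exact: treated plus untreated person-time sums
#' to the total follow-up time. Only binary (0/1) exposures are supported.
#'
#' @param cohort An [sncstm_cohort()].
#' @return Named list with `events_treated`, `py_treated`,
#'   `events_untreated`, `py_untreated`, suitable for [crude_rates()].
#' @export
person_time_by_exposure <- function(cohort) {
  stopifnot(inherits(cohort, "sncstm_cohort"))
  ev <- c(`0` = 0, `1` = 0)
  py <- c(`0` = 0, `1` = 0)
  for (r in cohort$records) {
    s <- r$visit_times
    K <- length(s) - 1L
    for (k in 0:K) {
      if (s[k + 1L] >= r$followup_time && !(k == 0L && r$followup_time == 0)) break
      a <- r$exposures[k + 1L]
      if (is.na(a)) next
      if (!a %in% c(0, 1)) {
        stop("person_time_by_exposure requires a binary 0/1 exposure")
      }
      upper <- if (k < K) min(s[k + 2L], r$followup_time) else r$followup_time
      key <- as.character(as.integer(a))
      py[key] <- py[key] + (upper - s[k + 1L])
      if (r$event == 1L && upper == r$followup_time &&
          (k == K || r$followup_time <= s[k + 2L])) {
        ev[key] <- ev[key] + 1
      }
    }
  }
  list(
    events_treated = unname(ev["1"]), py_treated = unname(py["1"]),
    events_untreated = unname(ev["0"]), py_untreated = unname(py["0"])
  )
}
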