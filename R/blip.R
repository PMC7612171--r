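#' Specify the causal blip parameterization
#'
#' The SNCSTM attaches a blip parameter `psi_k(l)` to each pair of visits
#' `0 <= k <= l <= K`: the additive effect of exposure at visit `k` on the
#' hazard within the window `[s_l, s_{l+1})`, when all later exposures are set
#' to zero. Each blip may additionally be modified linearly by measured
#' history at visit `k` (the constant basis term `1` is always included, plus
#' one term per confounder named in `modifiers`), and parameters may be shared
#' across visit pairs with equal lag `l - k`.
#'
#' Sharing is restricted to equal-lag merges: the sequential estimation order
#' (by ascending lag) requires that all parameters entering the weights and
#' blipped outcomes of a lag-`d` fit have lag `< d`, which cross-lag sharing
#' would break. A sharing map merging unequal lags is rejected here.
#'
#' @param K Number of post-baseline visits (visits are `0 ... K`).
#' @param modifiers Character vector of confounder names acting as effect
#'   modifiers (empty for no effect modification).
#' @param sharing `"none"` (a distinct parameter per `(k, l, basis)` triple),
#'   `"by_lag"` (one parameter per `(lag, basis)` pair, as in analyses that
#'   constrain the effect profile to be the same at every visit), or a
#'   function `(k, l, basis) -> id` returning a parameter id.
#' @return Object of class `blip_spec` with the parameter table `params`
#'   (columns `k`, `l`, `lag`, `basis`, `id`) and the ordered vector
#'   `parameter_ids`.
#' @export
blip_spec <- function(K, modifiers = character(0),
                      sharing = c("none", "by_lag")) {
  stopifnot(K >= 0)
  share_fun <-
    if (is.function(sharing)) {
      sharing
    } else {
      switch(match.arg(sharing),
        none   = function(k, l, basis) {
          paste0("psi_", k, "(", l, ")",
                 if (basis != "1") paste0(":", basis) else "")
        },
        by_lag = function(k, l, basis) {
          paste0("psi_lag", l - k,
                 if (basis != "1") paste0(":", basis) else "")
        }
      )
    }
  basis <- c("1", modifiers)
  grid <- expand.grid(k = 0:K, l = 0:K, basis = basis,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[grid$k <= grid$l, , drop = FALSE]
  grid$lag <- grid$l - grid$k
  grid$id <- mapply(share_fun, grid$k, grid$l, grid$basis)
  # equal-lag-only sharing: one id must not span two lags or two bases
  for (id in unique(grid$id)) {
    sub <- grid[grid$id == id, , drop = FALSE]
    if (length(unique(sub$lag)) > 1L) {
      stop("sharing map merges parameters of unequal lag (id '", id, "')")
    }
    if (length(unique(sub$basis)) > 1L) {
      stop("sharing map merges parameters of different modifier basis (id '",
           id, "')")
    }
  }
  grid <- grid[order(grid$lag, grid$k, match(grid$basis, basis)), ]
  rownames(grid) <- NULL
  structure(
    list(K = K, modifiers = modifiers, basis = basis,
         params = grid[, c("k", "l", "lag", "basis", "id")],
         parameter_ids = unique(grid$id)),
    class = "blip_spec"
  )
}

#' @export
print.blip_spec <- function(x, ...) {
  cat("Blip specification: K =", x$K, "\n")
  cat("  modifiers:", if (length(x$modifiers)) paste(x$modifiers, collapse = ", ")
      else "(none)", "\n")
  cat("  parameters:", length(x$parameter_ids), "distinct id(s) across",
      nrow(x$params), "(k, l, basis) triples\n")
  invisible(x)
}

# id of parameter (k, l, basis); errors if the triple is outside the spec
param_id <- function(spec, k, l, basis = "1") {
  row <- spec$params$k == k & spec$params$l == l & spec$params$basis == basis
  if (!any(row)) stop("no blip parameter for (k=", k, ", l=", l,
                      ", basis=", basis, ")")
  spec$params$id[row][1L]
}

# psi_k(l)(phi) evaluated on pseudo rows: the modifier-basis linear
# combination, with modifier values taken at visit k.
psi_value_rows <- function(psi, spec, k, l, rows) {
  out <- rep(0, nrow(rows))
  for (b in spec$basis) {
    id <- param_id(spec, k, l, b)
    if (!id %in% names(psi) || is.na(psi[[id]])) {
      stop("required blip parameter missing from psi: ", id)
    }
    phi <- if (b == "1") 1 else rows[[paste0(b, "_", k)]]
    out <- out + psi[[id]] * phi
  }
  out
}

#' Cumulative blip of one exposure up to a time point
#'
#' Evaluates `H_j(t)`: the cumulative log survival-probability adjustment
#' attributable to the exposure taken at visit `j`, accumulated from `s_j` to
#' `t`. Writing `lambda` for the window index with
#' `s_lambda <= t < s_{lambda+1}` (with `s_{K+1}` taken as the administrative
#' end),
#' \deqn{H_j(t) = A_j \Big\{ \sum_{m=j}^{\lambda-1} \psi_j(m)(\phi_j)
#'   (s_{m+1}-s_m) + \psi_j(\lambda)(\phi_j)(t - s_\lambda) \Big\},}
#' where `psi_j(m)(phi_j)` is the modifier-basis linear combination evaluated
#' at the subject's history at visit `j`.
#'
#' @param psi Named numeric vector of blip parameter estimates (names are
#'   parameter ids from the [blip_spec()]).
#' @param record A [subject_record()] with visit `j` attended.
#' @param spec The [blip_spec()].
#' @param j Visit index of the exposure (0-based).
#' @param t Time point, `t >= s_j`.
#' @return Scalar `H_j(t)`.
#' @export
cumulative_blip <- function(psi, record, spec, j, t) {
  s <- record$visit_times
  K <- length(s) - 1L
  if (t < s[j + 1L]) stop("t must be >= the visit time s_j")
  A_j <- record$exposures[j + 1L]
  if (is.na(A_j)) stop("exposure at visit ", j, " is unobserved")
  bounds <- c(s, record$admin_end)
  lambda <- max(which(bounds[seq_len(K + 1L)] <= t)) - 1L
  phi <- function(b) {
    if (b == "1") 1 else record$confounders[j + 1L, b]
  }
  psi_jl <- function(l) {
    v <- 0
    for (b in spec$basis) {
      id <- param_id(spec, j, l, b)
      if (!id %in% names(psi) || is.na(psi[[id]])) {
        stop("required blip parameter missing from psi: ", id)
      }
      v <- v + psi[[id]] * phi(b)
    }
    v
  }
  acc <- 0
  if (lambda > j) {
    for (m in j:(lambda - 1L)) {
      acc <- acc + psi_jl(m) * (s[m + 2L] - s[m + 1L])
    }
  }
  acc <- acc + psi_jl(lambda) * (t - s[lambda + 1L])
  A_j * acc
}

# Vectorized over pseudo rows of a common window l: sum_{j=k+1}^{l} H_j(Q),
# the log of the blip weight carried into lag-(l-k) fits.
blip_log_weight_rows <- function(rows, psi, spec, k, l) {
  out <- rep(0, nrow(rows))
  if (l <= k) return(out)
  for (j in (k + 1L):l) {
    inner <- rep(0, nrow(rows))
    if (j <= l - 1L) {
      for (m in j:(l - 1L)) {
        inner <- inner +
          psi_value_rows(psi, spec, j, m, rows) *
          (rows[[paste0("s_", m + 1L)]] - rows[[paste0("s_", m)]])
      }
    }
    inner <- inner + psi_value_rows(psi, spec, j, l, rows) *
      (rows$Q - rows[[paste0("s_", l)]])
    out <- out + rows[[paste0("A_", j)]] * inner
  }
  out
}

# Vectorized blipped outcome for rows of window l when estimating exposure k:
# I(T >= Q + delta_row) * exp{ delta_row * sum_{j=k+1}^{l} A_j psi_j(l)(phi_j) }
blip_outcome_rows <- function(rows, psi, spec, k, l) {
  adj <- rep(0, nrow(rows))
  if (l > k) {
    for (j in (k + 1L):l) {
      adj <- adj + rows[[paste0("A_", j)]] * psi_value_rows(psi, spec, j, l, rows)
    }
  }
  rows$surv_next * exp(rows$delta_row * adj)
}

#' Blipped survival outcome for one pseudo-individual row
#'
#' Transforms the observed interval survival indicator of a pseudo row into
#' the indicator that would have been observed had the exposures at visits
#' `k+1, ..., l` been removed: the raw indicator `I(T >= Q + delta_row)` is
#' multiplied by `exp{delta_row * sum_{j=k+1}^{l} A_j psi_j(l)(phi_j)}`
#' ("blipping down" the later exposures over the row's own interval). For
#' `k = l` the product is empty and the raw indicator is returned unchanged.
#'
#' @param row A single row of a [expand_cohort()] table with
#'   `outcome_known = TRUE` and `visit_index = l`.
#' @param psi Named vector of previously estimated blip parameters.
#' @param spec The [blip_spec()].
#' @param k Index of the exposure currently being estimated.
#' @param l Window index of the row.
#' @return Non-negative scalar outcome for the gamma score equation.
#' @export
blip_outcome <- function(row, psi, spec, k, l) {
  stopifnot(is.data.frame(row), nrow(row) == 1L)
  if (!isTRUE(row$outcome_known)) stop("outcome is not known for this row")
  if (row$visit_index != l) stop("row is not in window l")
  blip_outcome_rows(row, psi, spec, k, l)
}
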