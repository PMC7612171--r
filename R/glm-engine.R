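#' Weighted canonical-link GLM fit
#'
#' Thin, strict wrapper around iteratively reweighted least squares
#' (`stats::glm.fit`) for the three canonical families used by the
#' propensity-score and censoring models. Unlike the default fitter it treats
#' rank deficiency, non-convergence and perfect separation as hard errors, so
#' that downstream estimating equations are never built on a degenerate fit.
#'
#' @param design Numeric model matrix (include an intercept column yourself).
#' @param outcome Numeric response; for `"binomial"` it must lie in \{0, 1\}.
#' @param weights Positive prior weights.
#' @param family One of `"gaussian"` (identity link), `"binomial"` (logit) or
#'   `"poisson"` (log).
#' @return Object of class `canonical_glm`: coefficients, fitted values,
#'   raw residuals (`outcome - fitted`), family, convergence flag, iteration
#'   count and the max-norm of the weighted score at the solution.
#' @export
fit_canonical_glm <- function(design, outcome,
                              weights = rep(1, length(outcome)),
                              family = c("gaussian", "binomial", "poisson")) {
  family <- match.arg(family)
  X <- as.matrix(design)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- as.numeric(outcome)
  w <- as.numeric(weights)
  stopifnot(nrow(X) == length(y), length(w) == length(y))
  if (any(w <= 0) || anyNA(w)) stop("weights must be positive and non-missing")
  if (anyNA(X) || anyNA(y)) stop("design and outcome must be complete")
  qx <- qr(sqrt(w) * X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[seq.int(qx$rank + 1L, ncol(X))]]
    stop("design is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  if (family == "binomial") {
    if (!all(y %in% c(0, 1))) stop("binomial outcome must be 0/1")
    if (min(y) == max(y)) {
      stop("perfect separation: binomial outcome is constant")
    }
  }
  fam <- switch(family,
                gaussian = stats::gaussian(),
                binomial = stats::binomial(),
                poisson  = stats::poisson())
  fit <- withCallingHandlers(
    stats::glm.fit(X, y, weights = w, family = fam,
                   control = stats::glm.control(epsilon = 1e-12,
                                                maxit = 100L)),
    # continuous working weights are expected here (blip / censoring weights)
    warning = function(cond) {
      if (grepl("non-integer", conditionMessage(cond))) {
        invokeRestart("muffleWarning")
      }
    })
  mu <- fit$fitted.values
  score <- drop(crossprod(X, w * (y - mu)))
  if (family == "binomial" && all(abs(mu - y) < 1e-8)) {
    stop("perfect separation: fitted probabilities are degenerate")
  }
  if (!fit$converged) {
    stop("IRLS did not converge; score max-norm ", signif(max(abs(score)), 4))
  }
  structure(
    list(coefficients = stats::setNames(fit$coefficients, colnames(X)),
         fitted = mu, residuals = y - mu, family = family,
         converged = fit$converged, iterations = fit$iter,
         score_norm = max(abs(score))),
    class = "canonical_glm"
  )
}

#' @export
print.canonical_glm <- function(x, ...) {
  cat("Canonical GLM (", x$family, "), ", length(x$fitted), " observations\n",
      sep = "")
  print(signif(x$coefficients, 6))
  invisible(x)
}

#' Gamma log-link no-intercept score solver (the g-estimator core)
#'
#' Solves the estimating equation
#' \deqn{\sum_i w_i z_i \{ y_i \exp(-z_i^\top \psi) - 1 \} = 0,}
#' the score of a gamma-family GLM with log link and no intercept. For
#' survival g-estimation the outcome `y` is a (possibly blipped) survival
#' indicator and so contains zeros, which stock gamma-family software rejects;
#' the score itself is perfectly well defined with zeros, so it is solved
#' directly by damped Newton iteration (the score is coordinatewise monotone
#' for non-negative `y`, making damped Newton globally convergent in
#' practice), with a bracketing/bisection fallback in one dimension.
#'
#' @param blip_design Numeric matrix of blip covariates `z` (no intercept).
#' @param outcome Non-negative numeric vector `y`.
#' @param weights Positive weights.
#' @param tol Convergence tolerance on the score max-norm.
#' @param max_iter Newton iteration cap.
#' @return Object of class `blip_score_fit`: `coefficients` (the solution
#'   `psi_hat`), `score_norm` at the solution, `converged`, `iterations`.
#' @export
gamma_score_solve <- function(blip_design, outcome,
                              weights = rep(1, length(outcome)),
                              tol = 1e-10, max_iter = 100L) {
  Z <- as.matrix(blip_design)
  if (is.null(colnames(Z))) colnames(Z) <- paste0("z", seq_len(ncol(Z)))
  y <- as.numeric(outcome)
  w <- as.numeric(weights)
  stopifnot(nrow(Z) == length(y), length(w) == length(y))
  if (any(y < 0)) stop("outcome must be non-negative")
  if (any(w <= 0)) stop("weights must be positive")
  zero_col <- apply(abs(Z), 2L, max) == 0
  if (any(zero_col)) {
    stop("non-identifiable: blip covariate(s) identically zero: ",
         paste(colnames(Z)[zero_col], collapse = ", "))
  }
  pos <- y > 0
  if (!any(pos) || qr(Z[pos, , drop = FALSE])$rank < ncol(Z)) {
    stop("non-identifiable: blip design not of full rank on positive outcomes")
  }
  p <- ncol(Z)
  score <- function(psi) {
    mu <- y * exp(-drop(Z %*% psi))
    drop(crossprod(Z, w * (mu - 1)))
  }
  psi <- rep(0, p)
  s <- score(psi)
  converged <- max(abs(s)) < tol
  it <- 0L
  while (!converged && it < max_iter) {
    it <- it + 1L
    mu <- y * exp(-drop(Z %*% psi))
    J <- -crossprod(Z, (w * mu) * Z)   # Jacobian of the score, negative definite
    step <- tryCatch(-solve(J, s), error = function(e) NULL)
    if (is.null(step)) stop("singular score Jacobian at iteration ", it)
    lam <- 1
    repeat {
      s_new <- score(psi + lam * step)
      if (max(abs(s_new)) < max(abs(s)) || lam < 1e-10) break
      lam <- lam / 2
    }
    if (lam < 1e-10) {
      if (p == 1L) {
        psi <- bisect_scalar_score(function(x) score(x)[1L], tol)
        s <- score(psi)
        converged <- max(abs(s)) < tol
        break
      }
      dir <- which.max(abs(s))
      stop("score equation appears to have no root; unbounded direction: ",
           colnames(Z)[dir])
    }
    psi <- psi + lam * step
    s <- s_new
    converged <- max(abs(s)) < tol
  }
  if (!converged) {
    stop("gamma score solver did not converge; score max-norm ",
         signif(max(abs(s)), 4))
  }
  structure(
    list(coefficients = stats::setNames(psi, colnames(Z)),
         score_norm = max(abs(s)), converged = TRUE, iterations = it),
    class = "blip_score_fit"
  )
}

# Scalar fallback: expand a bracket around zero, then bisect on the score.
# The scalar score is strictly decreasing, so a sign change brackets the root.
bisect_scalar_score <- function(f, tol) {
  lo <- -1; hi <- 1
  while (f(lo) < 0 && lo > -1e3) lo <- lo * 2
  while (f(hi) > 0 && hi < 1e3) hi <- hi * 2
  if (f(lo) < 0 || f(hi) > 0) {
    stop("score equation has no sign change on [-1000, 1000]; no root")
  }
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) < tol || (hi - lo) < .Machine$double.eps * max(1, abs(mid))) {
      return(mid)
    }
    if (fm > 0) lo <- mid else hi <- mid
  }
  mid
}

#' @export
print.blip_score_fit <- function(x, ...) {
  cat("Gamma log-link score fit (", x$iterations, " Newton iterations, ",
      "score max-norm ", signif(x$score_norm, 3), ")\n", sep = "")
  print(signif(x$coefficients, 6))
  invisible(x)
}
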