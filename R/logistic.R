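#' Bernoulli log-likelihood of the logistic disease model
#'
#' Evaluates the log-likelihood of the logistic regression
#' \eqn{\mathrm{logit}\,\Pr(D=1|G,X) = \alpha'X + \mathrm{offset}} at supplied
#' coefficients, where the optional offset carries any genotype terms (so the
#' same evaluator serves the covariate-only null model and the genotype-coded
#' alternatives). Uses a log1p-exp formulation: never returns NaN for finite
#' inputs.
#'
#' @param table a [cohort_table()].
#' @param alpha numeric vector of length `table$L`, covariate coefficients
#'   (intercept first).
#' @param offset optional numeric vector (length n) of per-subject additions
#'   to the linear predictor, e.g. genotype effect terms.
#' @return The scalar log-likelihood.
#' @export
logistic_loglik <- function(table, alpha, offset = NULL) {
  stopifnot(length(alpha) == table$L)
  eta <- drop(table$covariates %*% alpha)
  if (!is.null(offset)) {
    stopifnot(length(offset) == table$n)
    eta <- eta + offset
  }
  # log L = sum D*eta - log(1+exp(eta))
  sum(table$phenotype * eta) - sum(log1pexp(eta))
}

# Newton/IRLS for logistic regression on a raw design matrix.
# Returns coefficients, fitted values, loglik, convergence info.
# Separation guard: |eta| > sep_bound while the likelihood is still
# climbing marks (quasi-)complete separation.
irls_logistic <- function(X, y, tol = 1e-10, maxit = 100L, sep_bound = 25) {
  beta <- numeric(ncol(X))
  eta <- drop(X %*% beta)
  ll <- sum(y * eta) - sum(log1pexp(eta))
  converged <- FALSE
  it <- 0L
  while (it < maxit) {
    it <- it + 1L
    mu <- expit(eta)
    w <- mu * (1 - mu)
    XtWX <- crossprod(X, X * w)
    score <- crossprod(X, y - mu)
    step <- tryCatch(solve(XtWX, score),
                     error = function(e) stop("singular information matrix in IRLS",
                                              call. = FALSE))
    # step-halving to guarantee likelihood ascent
    lam <- 1
    repeat {
      beta_new <- beta + lam * step
      eta_new <- drop(X %*% beta_new)
      ll_new <- sum(y * eta_new) - sum(log1pexp(eta_new))
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      lam <- lam / 2
      if (lam < 1e-10) { eta_new <- eta; ll_new <- ll; beta_new <- beta; break }
    }
    delta <- ll_new - ll
    beta <- drop(beta_new); eta <- eta_new; ll <- ll_new
    if (max(abs(eta)) > sep_bound)
      stop("separation detected: fitted probabilities saturating (|linear predictor| > ",
           sep_bound, ")", call. = FALSE)
    if (abs(delta) < tol) { converged <- TRUE; break }
  }
  list(coefficients = beta, fitted = expit(eta), eta = eta,
       loglik = ll, converged = converged, iterations = it)
}

#' Fit the covariate-only null logistic model
#'
#' Maximum-likelihood fit of \eqn{\mathrm{logit}\,\Pr(D=1|X) = \alpha'X}
#' (no genetic effect) by iteratively reweighted least squares. The fitted
#' values \eqn{\hat f_{0X_i} = 1/(1+\exp(-\hat\alpha'X_i))} are the estimated
#' baseline penetrances that every score statistic and the LRT reuse.
#'
#' @param table a [cohort_table()].
#' @param tol convergence tolerance on the log-likelihood change
#'   (default 1e-10).
#' @param maxit maximum IRLS iterations (default 100).
#' @return An object of class `null_fit`: list with `alpha_hat` (named
#'   L-vector), `fitted` (n-vector of baseline penetrances, strictly in
#'   (0,1)), `loglik`, `converged`, `iterations`.
#' @examples
#' tab <- cohort_table(rep(c(1, 0), 5), rep(0:1, 5))
#' fit_null(tab)$alpha_hat  # log(5/5) = 0
#' @export
fit_null <- function(table, tol = 1e-10, maxit = 100L) {
  res <- irls_logistic(table$covariates, table$phenotype,
                       tol = tol, maxit = maxit)
  if (!res$converged)
    stop("null model IRLS did not converge in ", maxit, " iterations",
         call. = FALSE)
  alpha <- res$coefficients
  names(alpha) <- colnames(table$covariates)
  structure(list(alpha_hat = alpha, fitted = res$fitted,
                 loglik = res$loglik, converged = res$converged,
                 iterations = res$iterations),
            class = "null_fit")
}

#' @export
print.null_fit <- function(x, ...) {
  cat("covariate-only logistic null fit\n")
  print(x$alpha_hat)
  cat(sprintf("logLik = %.6f (%d IRLS iterations)\n", x$loglik, x$iterations))
  invisible(x)
}
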