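# Genotype score weights a_i(z) = z*I(G=1) + I(G=2). The score numerator,
# all information blocks and the joint covariances are weighted sums in
# these a_i, so everything below reduces to a handful of crossproducts.
genotype_weights <- function(genotype, z) {
  z * (genotype == 1) + (genotype == 2)
}

# Relative threshold below which V(z) is declared degenerate (spec'd policy:
# monomorphic / near-monomorphic markers yield NA, not a garbage statistic).
DEGENERATE_REL <- 1e-12

#' Score numerator U(z) for one genetic model
#'
#' The gradient of the logistic log-likelihood with respect to the genetic
#' effect, evaluated at the covariate-only null fit:
#' \deqn{U(z) = \sum_i \{z I(G_i=1) + I(G_i=2)\}\{I(D_i=1) - \hat f_{0X_i}\}.}
#' `U(z)` is affine in `z`; `z` = 0, 1/2, 1 are the recessive, additive and
#' dominant scores.
#'
#' @param table a [cohort_table()].
#' @param fit a [fit_null()] result on the same table.
#' @param z genotype score in \[0, 1\].
#' @return Scalar U(z).
#' @export
score_numerator <- function(table, fit, z) {
  stopifnot(length(fit$fitted) == table$n, z >= 0, z <= 1)
  a <- genotype_weights(table$genotype, z)
  sum(a * (table$phenotype - fit$fitted))
}

#' Information matrix blocks for the genetic-effect score test
#'
#' Blocks of the expected information of the logistic model with genotype
#' term \eqn{z\beta I(G=1)+\beta I(G=2)}, evaluated at the null fit, with
#' per-subject weight \eqn{w_i = \hat f_{0X_i}(1-\hat f_{0X_i})}:
#' `I_beta` \eqn{= \sum a_i(z)^2 w_i}, `I_beta_alpha`
#' \eqn{= \sum a_i(z) w_i X_i} (L-vector), `I_alpha` \eqn{= X'WX}
#' (independent of z).
#'
#' @inheritParams score_numerator
#' @return List with `I_beta` (scalar), `I_beta_alpha` (L-vector),
#'   `I_alpha` (L x L).
#' @export
information_blocks <- function(table, fit, z) {
  a <- genotype_weights(table$genotype, z)
  w <- fit$fitted * (1 - fit$fitted)
  X <- table$covariates
  list(I_beta = sum(a * a * w),
       I_beta_alpha = drop(crossprod(X, a * w)),
       I_alpha = crossprod(X, X * w))
}

#' Null variance of U(z) with nuisance covariates profiled out
#'
#' The Schur complement
#' \eqn{V(z) = I_\beta(z) - I_{\beta\alpha}(z)' I_\alpha^{-1} I_{\beta\alpha}(z)},
#' i.e. the effective information for the genetic effect after eliminating
#' the covariate coefficients. Values below `1e-12 * I_beta` are reported as
#' `NA` (degenerate marker). A condition-number guard warns when `I_alpha`
#' is nearly singular.
#'
#' @param blocks result of [information_blocks()].
#' @return Scalar V(z), or `NA` with a warning when degenerate.
#' @export
score_variance <- function(blocks) {
  R <- tryCatch(chol(blocks$I_alpha),
                error = function(e) stop("singular covariate information matrix I_alpha",
                                         call. = FALSE))
  d <- diag(R)
  if (max(d)^2 / min(d)^2 > 1e10)
    warning("covariate information matrix is ill-conditioned (condition number > 1e10)")
  u <- backsolve(R, blocks$I_beta_alpha, transpose = TRUE)
  V <- blocks$I_beta - sum(u * u)
  if (!is.finite(V) || V <= DEGENERATE_REL * max(blocks$I_beta, 1e-300)) {
    warning("degenerate variance: V(z) ~ 0 (monomorphic or near-monomorphic marker)")
    return(NA_real_)
  }
  V
}

#' Single-model score test S(z)
#'
#' Standardized score statistic \eqn{S(z) = U(z)/\sqrt{V(z)}}, standard
#' normal under the null hypothesis of no genetic effect, with two-sided
#' p-value \eqn{2\{1-\Phi(|S|)\}}. `z` = 0, 1/2, 1 give the recessive,
#' additive (Cochran-Armitage-type) and dominant tests; with intercept-only
#' covariates S(z) reduces exactly to the classical trend test.
#'
#' @inheritParams score_numerator
#' @return An object of class `score_result`: list with `z`, `U`, `V`, `S`,
#'   `p_two_sided` (all `NA` except `z`, `U` when the variance degenerates).
#' @export
score_statistic <- function(table, fit, z) {
  U <- score_numerator(table, fit, z)
  V <- score_variance(information_blocks(table, fit, z))
  if (is.na(V))
    return(structure(list(z = z, U = U, V = NA_real_, S = NA_real_,
                          p_two_sided = NA_real_), class = "score_result"))
  S <- U / sqrt(V)
  structure(list(z = z, U = U, V = V, S = S,
                 p_two_sided = 2 * stats::pnorm(-abs(S))),
            class = "score_result")
}

#' @export
print.score_result <- function(x, ...) {
  cat(sprintf("score test, z = %g: S = %.4f, p = %.3g (U = %.4f, V = %.4f)\n",
              x$z, x$S, x$p_two_sided, x$U, x$V))
  invisible(x)
}

#' Joint null covariance and correlation of two score statistics
#'
#' From the two-genotype-term logistic model embedding both scores, the
#' covariance of \eqn{(U(z_1), U(z_2))} is the 2x2 Schur complement
#' \eqn{C = I_{\beta_1\beta_2} - B I_\alpha^{-1} B'} with B the 2 x L
#' cross-information; the correlation of \eqn{(S(z_1), S(z_2))} is
#' \eqn{\rho = C_{12}/\sqrt{C_{11}C_{22}}}. `C11`/`C22` equal
#' [score_variance()] at `z1`/`z2`.
#'
#' @inheritParams score_numerator
#' @param z1,z2 the two genotype scores in \[0, 1\].
#' @return List with `z1`, `z2`, `C` (2x2) and `rho` (`NA` when a diagonal
#'   degenerates).
#' @export
pair_correlation <- function(table, fit, z1, z2) {
  a1 <- genotype_weights(table$genotype, z1)
  a2 <- genotype_weights(table$genotype, z2)
  w <- fit$fitted * (1 - fit$fitted)
  X <- table$covariates
  A <- cbind(a1, a2)
  Ibb <- crossprod(A, A * w)
  B <- crossprod(A * w, X)                   # 2 x L
  R <- chol(crossprod(X, X * w))
  U <- backsolve(R, t(B), transpose = TRUE)  # L x 2
  C <- Ibb - crossprod(U)
  C <- (C + t(C)) / 2
  degen <- diag(C) <= DEGENERATE_REL * pmax(diag(Ibb), 1e-300)
  rho <- if (any(degen)) NA_real_ else C[1, 2] / sqrt(C[1, 1] * C[2, 2])
  list(z1 = z1, z2 = z2, C = C, rho = rho)
}
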