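#' Two-degree-of-freedom likelihood ratio test for genotype effect
#'
#' Fits the saturated-genotype logistic model
#' \eqn{\mathrm{logit}\,\Pr(D=1|G,X) = \alpha'X + \beta_1 I(G=1) + (\beta_1+\beta_2) I(G=2)}
#' and compares it to the covariate-only null by a likelihood ratio test,
#' asymptotically chi-square with 2 degrees of freedom. This is the
#' model-free comparator: robust to the genetic model but less efficient
#' than MAX3 because it ignores the penetrance ordering. When a genotype
#' class is absent its contrast is inestimable: the column is dropped, the
#' degrees of freedom reduced, and `df` records the actual value.
#'
#' @param table a [cohort_table()].
#' @param null_fit optional pre-computed [fit_null()].
#' @return An object of class `lrt_result`: list with `stat` (twice the
#'   log-likelihood difference, clipped at 0), `df`, `p_value`, `beta1_hat`,
#'   `beta2_hat` (the heterozygote effect and the homozygote increment; `NA`
#'   when inestimable).
#' @export
lrt_test <- function(table, null_fit = NULL) {
  if (is.null(null_fit)) null_fit <- fit_null(table)
  G <- table$genotype
  I1 <- as.numeric(G == 1)
  I2 <- as.numeric(G == 2)
  counts <- tabulate(factor(G, levels = 0:2), nbins = 3L)
  if (sum(counts > 0L) <= 1L) {
    warning("monomorphic marker: LRT undefined")
    return(structure(list(stat = NA_real_, df = NA_integer_,
                          p_value = NA_real_, beta1_hat = NA_real_,
                          beta2_hat = NA_real_), class = "lrt_result"))
  }
  # parameterization: columns (I1 + I2, I2) carry (beta1, beta2)
  gcols <- cbind(b1 = I1 + I2, b2 = I2)
  keep <- c(counts[2] > 0L || counts[3] > 0L, counts[3] > 0L)
  # with no heterozygotes the two columns coincide; drop the duplicate
  if (counts[2] == 0L && counts[3] > 0L) keep <- c(TRUE, FALSE)
  gcols <- gcols[, keep, drop = FALSE]
  Xalt <- cbind(table$covariates, gcols)
  alt <- irls_logistic(Xalt, table$phenotype)
  if (!alt$converged) stop("alternative model IRLS did not converge",
                           call. = FALSE)
  stat <- max(0, 2 * (alt$loglik - null_fit$loglik))
  df <- ncol(gcols)
  coefs <- alt$coefficients[table$L + seq_len(df)]
  b1 <- if (keep[1]) coefs[1] else NA_real_
  b2 <- if (length(coefs) > 1) coefs[2] else NA_real_
  structure(list(stat = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                 beta1_hat = unname(b1), beta2_hat = unname(b2)),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("genotype LRT: stat = %.4f on %d df, p = %.4g\n",
              x$stat, x$df, x$p_value))
  invisible(x)
}

#' Original covariate-free MAX3 test
#'
#' The classical robust trend-based test using only the 2x3
#' phenotype-by-genotype table: identical machinery to [cmax3_test()] with
#' the covariate matrix reduced to the intercept, under which each S(z)
#' collapses to the Cochran-Armitage trend test with scores (0, z, 1) and
#' \eqn{\Sigma} to the classical trend-test correlation matrix. Provided as
#' the comparator that the covariate-adjusted test supersedes when
#' covariates matter: it is not valid under covariate confounding.
#'
#' @param phenotype binary 0/1 vector.
#' @param genotype 0/1/2 risk-allele count vector.
#' @param include_lrt also attach the (covariate-free) 2-df LRT.
#' @return A `max3_result`, as from [cmax3_test()].
#' @export
omax3_test <- function(phenotype, genotype, include_lrt = TRUE) {
  tab <- cohort_table(phenotype, genotype, covariates = NULL)
  cmax3_test(tab, include_lrt = include_lrt)
}
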