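MODEL_LABELS <- c("REC", "ADD", "DOM")
MODEL_SCORES <- c(0, 0.5, 1)

# Fast shared core: per-model statistics S(0), S(1/2), S(1), their null
# correlation matrix, the max statistic and its asymptotic p-value, from raw
# vectors. Used by cmax3_test / omax3_test and the simulation inner loop.
# Returns NULL-safe list; na_reason is NA_character_ on success.
cmax3_core <- function(D, G, X, fitted = NULL) {
  if (is.null(fitted)) {
    fit <- irls_logistic(X, D)
    if (!fit$converged) stop("null model IRLS did not converge", call. = FALSE)
    fitted <- fit$fitted
  }
  w <- fitted * (1 - fitted)
  r <- D - fitted
  I1 <- as.numeric(G == 1)
  I2 <- as.numeric(G == 2)
  A <- cbind(I2, 0.5 * I1 + I2, I1 + I2)
  dimnames(A) <- list(NULL, MODEL_LABELS)
  Ibb <- crossprod(A, A * w)
  Bm <- crossprod(A * w, X)
  R <- chol(crossprod(X, X * w))
  Um <- backsolve(R, t(Bm), transpose = TRUE)
  C <- Ibb - crossprod(Um)
  C <- (C + t(C)) / 2
  dC <- diag(C)
  if (any(dC <= DEGENERATE_REL * pmax(diag(Ibb), 1e-300))) {
    return(list(S = rep(NA_real_, 3), sigma = matrix(NA_real_, 3, 3),
                t = NA_real_, p_value = NA_real_,
                p_model = rep(NA_real_, 3), best_model = NA_character_,
                U = unname(drop(crossprod(A, r))),
                V = unname(ifelse(dC > 0, dC, NA_real_)),
                na_reason = "degenerate variance"))
  }
  sd_ <- sqrt(dC)
  sigma <- C / tcrossprod(sd_)
  diag(sigma) <- 1
  dimnames(sigma) <- list(MODEL_LABELS, MODEL_LABELS)
  U <- unname(drop(crossprod(A, r)))
  S <- U / unname(sd_)
  tmax <- max(abs(S))
  list(S = S, sigma = sigma, t = tmax,
       p_value = mvn_rectangle(tmax, sigma),
       p_model = 2 * stats::pnorm(-abs(S)),
       best_model = MODEL_LABELS[which.max(abs(S))],
       U = U, V = unname(dC), na_reason = NA_character_)
}

#' Null correlation matrix of the three per-model score statistics
#'
#' Assembles the 3x3 correlation matrix \eqn{\Sigma} of
#' \eqn{(S(0), S(1/2), S(1))} under the null, from the pairwise joint score
#' covariances (see [pair_correlation()]). Symmetric with unit diagonal by
#' construction.
#'
#' @inheritParams score_numerator
#' @return 3x3 correlation matrix, or a matrix of `NA` when any pair is
#'   degenerate (e.g. a missing genotype class).
#' @export
sigma_matrix <- function(table, fit) {
  zs <- MODEL_SCORES
  sig <- diag(3)
  for (i in 1:2) for (j in (i + 1):3) {
    pc <- pair_correlation(table, fit, zs[i], zs[j])
    if (is.na(pc$rho)) return(matrix(NA_real_, 3, 3))
    sig[i, j] <- sig[j, i] <- pc$rho
  }
  dimnames(sig) <- list(MODEL_LABELS, MODEL_LABELS)
  sig
}

#' Covariate-adjusted MAX3 association test
#'
#' The robust test for a diallelic marker when the genetic model is unknown:
#' computes the covariate-adjusted score statistics S(0), S(1/2) and S(1)
#' (optimal for the recessive, additive and dominant models), takes
#' \deqn{T = \max(|S(0)|, |S(1/2)|, |S(1)|),}
#' and obtains the asymptotic p-value as the probability that the maximum
#' absolute component of a trivariate normal with the estimated null
#' correlation matrix \eqn{\Sigma} exceeds T (see [mvn_rectangle()]).
#' The result is invariant to swapping the case/control labels and, up to
#' the REC/DOM label exchange, to recoding the risk allele.
#'
#' @param table a [cohort_table()], or anything coercible via
#'   `cohort_table()` when given as a 2+ column matrix/data frame in the
#'   (phenotype, genotype, covariates...) layout.
#' @param fit optional pre-computed [fit_null()] (reused across markers in
#'   batch screening).
#' @param include_lrt also run the 2-df likelihood ratio test and attach
#'   `lrt_stat`, `lrt_p` (default `TRUE`).
#' @return An object of class `max3_result`: list with `t` (the statistic),
#'   `sigma` (3x3 null correlation), `p_value`, `per_model` (named list of
#'   [score_statistic()] results for REC/ADD/DOM), `best_model` (arg-max
#'   label; ties broken in REC, ADD, DOM order), `lrt_stat`, `lrt_p`, and
#'   `na_reason` (`NA` unless the statistic is undefined, e.g. "degenerate
#'   variance" for a monomorphic marker).
#' @examples
#' tab <- simulate_cohort(sim_config(n = 500, maf = 0.3, beta = 0.6,
#'                                   model = "ADD", seed = 1))
#' cmax3_test(tab)
#' @export
cmax3_test <- function(table, fit = NULL, include_lrt = TRUE) {
  if (!inherits(table, "cohort_table")) {
    m <- as.matrix(table)
    cov <- if (ncol(m) > 2) m[, -(1:2), drop = FALSE] else NULL
    table <- cohort_table(m[, 1], m[, 2], covariates = cov)
  }
  if (is.null(fit)) fit <- fit_null(table)
  core <- cmax3_core(table$phenotype, table$genotype, table$covariates,
                     fitted = fit$fitted)
  per_model <- stats::setNames(lapply(1:3, function(i) {
    structure(list(z = MODEL_SCORES[i], U = core$U[i], V = core$V[i],
                   S = core$S[i], p_two_sided = core$p_model[i]),
              class = "score_result")
  }), MODEL_LABELS)
  res <- structure(
    list(t = core$t, sigma = core$sigma, p_value = core$p_value,
         per_model = per_model, best_model = core$best_model,
         lrt_stat = NA_real_, lrt_p = NA_real_, df = NA_integer_,
         na_reason = core$na_reason, n = table$n),
    class = "max3_result")
  if (include_lrt && is.na(core$na_reason)) {
    lrt <- lrt_test(table, fit)
    res$lrt_stat <- lrt$stat
    res$lrt_p <- lrt$p_value
    res$df <- lrt$df
  }
  res
}

#' @export
print.max3_result <- function(x, ...) {
  if (!is.na(x$na_reason)) {
    cat("MAX3 test: NA (", x$na_reason, ")\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf("covariate-adjusted MAX3 test (n = %d)\n", x$n))
  cat(sprintf("  statistic T = %.4f, asymptotic p = %.4g, best-fitting model: %s\n",
              x$t, x$p_value, x$best_model))
  for (lab in MODEL_LABELS) {
    pm <- x$per_model[[lab]]
    cat(sprintf("  S(%-3s) [z=%g]: S = %8.4f, p = %.4g\n",
                lab, pm$z, pm$S, pm$p_two_sided))
  }
  if (!is.na(x$lrt_stat))
    cat(sprintf("  LRT (%d df): stat = %.4f, p = %.4g\n",
                x$df, x$lrt_stat, x$lrt_p))
  cat("  null correlation of (S(0), S(1/2), S(1)):\n")
  print(round(x$sigma, 4))
  invisible(x)
}
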