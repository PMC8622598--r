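test_that("U(z) is the score: matches the finite-difference gradient in beta", {
  tab <- random_table(12, n = 400, beta = 0.2)
  fit <- fit_null(tab)
  for (z in c(0, 0.5, 1, 0.3)) {
    a <- z * (tab$genotype == 1) + (tab$genotype == 2)
    fd <- fd_grad(function(b) logistic_loglik(tab, fit$alpha_hat,
                                              offset = b[1] * a), 0)
    U <- score_numerator(tab, fit, z)
    expect_equal(U, fd, tolerance = 1e-4)
  }
})

test_that("U(z) is affine in z; monomorphic tables give U = 0", {
  tab <- random_table(3, n = 150)
  fit <- fit_null(tab)
  u0 <- score_numerator(tab, fit, 0)
  u1 <- score_numerator(tab, fit, 1)
  expect_equal(score_numerator(tab, fit, 0.5), (u0 + u1) / 2,
               tolerance = 1e-12)
  expect_equal(score_numerator(tab, fit, 0.25), 0.75 * u0 + 0.25 * u1,
               tolerance = 1e-12)

  mono <- cohort_table(rep(c(1, 0), 10), rep(0, 20))
  fitm <- fit_null(mono)
  for (z in c(0, 0.5, 1))
    expect_identical(score_numerator(mono, fitm, z), 0)
})

test_that("information blocks match direct evaluation and FD Hessian", {
  # all fitted 0.5, intercept-only: I_beta(z) = 0.25 (z^2 n1 + n2)
  tab <- cohort_table(rep(c(1, 0), each = 10),
                      rep(c(0, 1, 2, 1), 5))
  fit <- fit_null(tab)
  n1 <- sum(tab$genotype == 1); n2 <- sum(tab$genotype == 2)
  for (z in c(0, 0.5, 1)) {
    bl <- information_blocks(tab, fit, z)
    expect_equal(bl$I_beta, 0.25 * (z^2 * n1 + n2), tolerance = 1e-10)
  }

  # I_alpha = negative FD Hessian of the null log-likelihood at alpha_hat
  tab2 <- random_table(9, n = 300)
  fit2 <- fit_null(tab2)
  bl2 <- information_blocks(tab2, fit2, 0.5)
  H <- fd_hess(function(a) logistic_loglik(tab2, a), unname(fit2$alpha_hat))
  expect_equal(unname(bl2$I_alpha), -H, tolerance = 1e-4)

  # z = 0 ignores heterozygotes entirely
  keep <- tab2$genotype != 1
  tab3 <- cohort_table(tab2$phenotype[keep], tab2$genotype[keep],
                       covariates = tab2$covariates[keep, -1, drop = FALSE])
  fit3 <- list(fitted = fit2$fitted[keep])
  bl_full <- information_blocks(tab2, fit2, 0)
  bl_sub <- information_blocks(tab3, fit3, 0)
  expect_equal(bl_full$I_beta, bl_sub$I_beta, tolerance = 1e-12)
  expect_equal(unname(bl_full$I_beta_alpha[1]),
               unname(bl_sub$I_beta_alpha[1]), tolerance = 1e-12)
})

test_that("V(z) equals the classical trend-test variance without covariates", {
  set.seed(21)
  tab <- cohort_table(rbinom(400, 1, 0.5),
                      sample(0:2, 400, TRUE, c(0.49, 0.42, 0.09)))
  fit <- fit_null(tab)
  n_j <- tabulate(factor(tab$genotype, levels = 0:2), nbins = 3)
  R <- sum(tab$phenotype); N <- tab$n
  for (z in c(0, 0.5, 1)) {
    s <- c(0, z, 1)
    V_catt <- R * (N - R) / N^2 * (sum(n_j * s^2) - sum(n_j * s)^2 / N)
    expect_equal(score_variance(information_blocks(tab, fit, z)), V_catt,
                 tolerance = 1e-10)
  }
})

test_that("V is a quadratic in z, bounded by I_beta, degenerate -> NA", {
  for (seed in 1:5) {
    tab <- random_table(seed + 400, n = 250)
    fit <- fit_null(tab)
    Vz <- vapply(c(0, 0.5, 1), function(z)
      score_variance(information_blocks(tab, fit, z)), numeric(1))
    # 3-point Lagrange interpolation predicts any other z
    zq <- 0.3
    pred <- Vz[1] * (zq - 0.5) * (zq - 1) / (0.5) +
      Vz[2] * (zq - 0) * (zq - 1) / (-0.25) +
      Vz[3] * (zq - 0) * (zq - 0.5) / (0.5)
    expect_equal(score_variance(information_blocks(tab, fit, zq)), pred,
                 tolerance = 1e-8)
    for (z in c(0, 0.5, 1)) {
      bl <- information_blocks(tab, fit, z)
      expect_lte(score_variance(bl), bl$I_beta + 1e-10)
    }
  }
  mono <- cohort_table(rep(c(1, 0), 10), rep(0, 20))
  fitm <- fit_null(mono)
  expect_warning(V <- score_variance(information_blocks(mono, fitm, 0.5)),
                 "degenerate")
  expect_true(is.na(V))
  res <- suppressWarnings(score_statistic(mono, fitm, 0.5))
  expect_true(is.na(res$S) && is.na(res$p_two_sided))
})

test_that("S(z) flips sign under label flip and maps S(z) -> -S(1-z) under allele recoding", {
  for (seed in c(5, 6, 7)) {
    tab <- random_table(seed, n = 350, beta = 0.3)
    fit <- fit_null(tab)
    tabf <- flip_phenotype(tab)
    fitf <- fit_null(tabf)
    taba <- flip_alleles(tab)
    fita <- fit_null(taba)
    for (z in c(0, 0.5, 1)) {
      S <- score_statistic(tab, fit, z)$S
      expect_equal(score_statistic(tabf, fitf, z)$S, -S, tolerance = 1e-8)
      expect_equal(score_statistic(taba, fita, 1 - z)$S, -S,
                   tolerance = 1e-8)
    }
  }
})

test_that("pair_correlation is consistent with score_variance and a full-matrix oracle", {
  tab <- random_table(31, n = 300)
  fit <- fit_null(tab)
  pc <- pair_correlation(tab, fit, 0, 1)
  expect_equal(pc$C[1, 1],
               score_variance(information_blocks(tab, fit, 0)),
               tolerance = 1e-10)
  expect_equal(pc$C[2, 2],
               score_variance(information_blocks(tab, fit, 1)),
               tolerance = 1e-10)
  expect_equal(pair_correlation(tab, fit, 0.5, 0.5)$rho, 1, tolerance = 1e-10)
  expect_true(abs(pc$rho) <= 1)

  # oracle: invert the full (2+L) bordered information matrix of the
  # two-genotype-term embedding model; the beta-block of its inverse is C^-1
  w <- fit$fitted * (1 - fit$fitted)
  a1 <- 0 * (tab$genotype == 1) + (tab$genotype == 2)
  a2 <- 1 * (tab$genotype == 1) + (tab$genotype == 2)
  Mfull <- crossprod(cbind(a1, a2, tab$covariates) * sqrt(w))
  C_oracle <- solve(solve(Mfull)[1:2, 1:2])
  expect_equal(unname(pc$C), unname(C_oracle), tolerance = 1e-8)
})
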