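test_that("sigma_matrix: unit diagonal, symmetry, agreement with the core", {
  tab <- random_table(101, n = 400)
  fit <- fit_null(tab)
  sig <- sigma_matrix(tab, fit)
  expect_equal(diag(sig), c(REC = 1, ADD = 1, DOM = 1))
  expect_equal(sig, t(sig))
  res <- cmax3_test(tab, fit = fit, include_lrt = FALSE)
  expect_equal(unname(res$sigma), unname(sig), tolerance = 1e-10)
})

test_that("sigma_matrix is PSD across a sweep of simulated tables", {
  worst <- Inf
  for (seed in 1:200) {
    tab <- random_table(seed + 9000, n = 200, maf = runif(1, 0.1, 0.5))
    sig <- sigma_matrix(tab, fit_null(tab))
    if (anyNA(sig)) next  # degenerate class: NA by contract
    worst <- min(worst, min(eigen(sig, symmetric = TRUE,
                                  only.values = TRUE)$values))
  }
  expect_gte(worst, -1e-10)
})

test_that("mvn_rectangle closed forms, bounds and determinism", {
  expect_equal(mvn_rectangle(0, diag(3)), 1)
  for (t in c(0.7, 2, 3.5, 5.45)) {
    # cancellation-free expansions of 1 - (1-q)^k with q = 2*Phi(-t)
    q <- 2 * pnorm(-t)
    expect_equal(mvn_rectangle(t, diag(3)), 3 * q - 3 * q^2 + q^3,
                 tolerance = 1e-10)
    expect_equal(mvn_rectangle(t, matrix(1, 3, 3)), q, tolerance = 1e-12)
    expect_equal(mvn_rectangle(t, diag(2)), 2 * q - q^2, tolerance = 1e-10)
    expect_equal(mvn_rectangle(t, diag(1)), q, tolerance = 1e-12)
  }
  S <- matrix(c(1, .6, .3, .6, 1, .8, .3, .8, 1), 3)
  expect_identical(mvn_rectangle(2.5, S), mvn_rectangle(2.5, S))
  # monotone decreasing in t
  ts <- seq(0.2, 6, by = 0.2)
  ps <- vapply(ts, mvn_rectangle, numeric(1), sigma = S)
  expect_true(all(diff(ps) < 0))
  # small p-values are not truncated
  expect_gt(mvn_rectangle(9, S), 0)
  expect_lt(mvn_rectangle(9, S), 1e-16)
  # invalid sigma rejected
  expect_error(mvn_rectangle(1, matrix(c(1, 2, 2, 1), 2)), "positive")
})

test_that("near-perfect correlation collapses continuously", {
  mk <- function(r12) matrix(c(1, r12, .5, r12, 1, .5, .5, .5, 1), 3)
  p_collapsed <- mvn_rectangle(2, mk(1 - 1e-12))
  p_2d <- mvn_rectangle(2, matrix(c(1, .5, .5, 1), 2))
  expect_equal(p_collapsed, p_2d, tolerance = 1e-12)
  p_near <- mvn_rectangle(2, mk(1 - 1e-9))
  expect_equal(p_near, p_2d, tolerance = 1e-4)
})

test_that("sigma and the asymptotic p agree with a Monte-Carlo null study", {
  # moderate covariates, n = 1000, MAF = 0.3: empirical correlation of the
  # score triple across replicates vs the analytic sigma, entrywise
  cfg <- sim_config(n = 1000, maf = 0.3, alpha = c(-5, 1, 0.5), beta = 0,
                    seed = 2024)
  B <- 3000
  Smat <- matrix(NA_real_, B, 3)
  sig_sum <- matrix(0, 3, 3)
  for (b in seq_len(B)) {
    raw <- cmax3:::sample_case_control(cfg, cmax3:::derive_seed(2024, b))
    core <- cmax3:::cmax3_core(raw$D, raw$G, raw$X)
    Smat[b, ] <- core$S
    sig_sum <- sig_sum + core$sigma
  }
  emp <- cor(Smat)
  expect_equal(unname(emp), unname(sig_sum / B), tolerance = 0.04)
  # rho(0,1) is the smallest correlation (property, flagged if violated)
  sig <- sig_sum / B
  expect_lte(sig[1, 3], sig[1, 2] + 1e-8)
  expect_lte(sig[1, 3], sig[2, 3] + 1e-8)
  # scores are marginally standard normal under the null
  expect_lt(max(abs(colMeans(Smat))), 0.06)
  expect_lt(max(abs(apply(Smat, 2, var) - 1)), 0.08)
})

test_that("cmax3_test pipeline: strong additive signal is detected as ADD", {
  hits <- 0; best_add <- 0
  for (r in 1:40) {
    cfg <- sim_config(n = 2000, maf = 0.3, beta = 1.5, model = "ADD",
                      seed = 5000 + r)
    res <- cmax3_test(simulate_cohort(cfg), include_lrt = FALSE)
    hits <- hits + (res$p_value < 1e-6)
    best_add <- best_add + (res$best_model == "ADD")
  }
  expect_gte(hits / 40, 0.95)
  expect_gte(best_add / 40, 0.95)
})

test_that("max statistic, best model and the p-value floor behave by contract", {
  tab <- random_table(64, n = 500, beta = 0.4)
  res <- cmax3_test(tab)
  absS <- abs(vapply(res$per_model, function(m) m$S, numeric(1)))
  expect_equal(res$t, max(absS))
  expect_equal(res$best_model, names(absS)[which.max(absS)])
  # maximum can only lose significance relative to the best single model
  expect_gte(res$p_value, min(vapply(res$per_model,
                                     function(m) m$p_two_sided,
                                     numeric(1))) - 1e-12)
  expect_true(res$p_value >= 0 && res$p_value <= 1)
})

test_that("monomorphic marker yields NA with a machine-readable reason", {
  tab <- cohort_table(rep(c(1, 0), 20), rep(0, 40))
  res <- suppressWarnings(cmax3_test(tab))
  expect_true(is.na(res$p_value))
  expect_equal(res$na_reason, "degenerate variance")
})

test_that("p-value is invariant under label flip and allele recoding", {
  for (seed in c(81, 82, 83)) {
    tab <- random_table(seed, n = 400, beta = 0.3, z = 1)
    p0 <- cmax3_test(tab, include_lrt = FALSE)$p_value
    expect_equal(cmax3_test(flip_phenotype(tab), include_lrt = FALSE)$p_value,
                 p0, tolerance = 1e-8)
    resa <- cmax3_test(flip_alleles(tab), include_lrt = FALSE)
    expect_equal(resa$p_value, p0, tolerance = 1e-8)
  }
})
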