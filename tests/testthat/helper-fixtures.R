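# Shared fixtures and independent oracles. Everything is generated in code;
# no stored data. Oracles here are deliberately naive (direct summation,
# finite differences, generic optimizers, contingency-table formulas) and
# must stay independent of the package's own computational path.

# Prospective random cohort: genotype in HWE, two covariates, Bernoulli
# disease draw. Small-n workhorse for property tests (distinct from the
# retrospective simulation module).
random_table <- function(seed, n = 300, maf = 0.3, beta = 0, z = 0.5,
                         alpha = c(-0.2, 0.3, -0.4)) {
  set.seed(seed)
  G <- sample(0:2, n, replace = TRUE,
              prob = c((1 - maf)^2, 2 * maf * (1 - maf), maf^2))
  X2 <- stats::rbinom(n, 1, 0.5)
  X3 <- stats::runif(n)
  eta <- alpha[1] + alpha[2] * X2 + alpha[3] * X3 +
    beta * (z * (G == 1) + (G == 2))
  D <- stats::rbinom(n, 1, stats::plogis(eta))
  if (length(unique(D)) < 2) D[1:2] <- c(0, 1)
  if (length(unique(G)) < 2) G[1:2] <- c(0, 1)
  cohort_table(D, G, covariates = cbind(X2 = X2, X3 = X3))
}

flip_phenotype <- function(tab)
  cohort_table(1 - tab$phenotype, tab$genotype,
               covariates = tab$covariates[, -1, drop = FALSE])

flip_alleles <- function(tab)
  cohort_table(tab$phenotype, 2 - tab$genotype,
               covariates = tab$covariates[, -1, drop = FALSE])

# Central finite-difference gradient and Hessian of scalar fn at x.
fd_grad <- function(fn, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h
    (fn(x + e) - fn(x - e)) / (2 * h)
  }, numeric(1))
}

fd_hess <- function(fn, x, h = 1e-5) {
  k <- length(x)
  H <- matrix(NA_real_, k, k)
  for (i in 1:k) for (j in i:k) {
    ei <- numeric(k); ei[i] <- h
    ej <- numeric(k); ej[j] <- h
    H[i, j] <- H[j, i] <-
      (fn(x + ei + ej) - fn(x + ei - ej) - fn(x - ei + ej) + fn(x - ei - ej)) /
      (4 * h * h)
  }
  H
}

# Textbook Cochran-Armitage trend statistic from the 2x3 counts with
# genotype scores (0, z, 1).
catt_z <- function(D, G, z = 0.5) {
  s <- c(0, z, 1)
  n_j <- tabulate(factor(G, levels = 0:2), nbins = 3)
  r_j <- tabulate(factor(G[D == 1], levels = 0:2), nbins = 3)
  N <- sum(n_j); R <- sum(r_j)
  U <- sum(s * (r_j - n_j * R / N))
  V <- R * (N - R) / N^2 * (sum(n_j * s^2) - sum(n_j * s)^2 / N)
  U / sqrt(V)
}

# Naive retrospective sampler: the literal draw-D-and-thin scheme, used as
# a distributional oracle for the package's envelope rejection sampler.
naive_retrospective <- function(config, seed) {
  set.seed(seed)
  n_case <- round(config$n * config$case_fraction)
  n_ctrl <- config$n - n_case
  a <- config$alpha; gp <- c((1 - config$maf)^2,
                             2 * config$maf * (1 - config$maf), config$maf^2)
  geff <- c(0, config$z * config$beta, config$beta)
  cases <- list(); ctrls <- list(); nc <- 0; nt <- 0
  while (nc < n_case || nt < n_ctrl) {
    m <- 50000
    x2 <- rbinom(m, 1, 0.5); x3 <- runif(m)
    g <- sample(0:2, m, TRUE, prob = gp)
    f <- plogis(a[1] + a[2] * x2 + a[3] * x3 + geff[g + 1])
    d <- rbinom(m, 1, f)
    cases[[length(cases) + 1]] <- cbind(x2, x3, g)[d == 1, , drop = FALSE]
    ctrls[[length(ctrls) + 1]] <- cbind(x2, x3, g)[d == 0, , drop = FALSE]
    nc <- nc + sum(d == 1); nt <- nt + sum(d == 0)
  }
  cs <- do.call(rbind, cases)[seq_len(n_case), , drop = FALSE]
  ct <- do.call(rbind, ctrls)[seq_len(n_ctrl), , drop = FALSE]
  list(D = rep(c(1, 0), c(n_case, n_ctrl)),
       G = c(cs[, 3], ct[, 3]),
       X2 = c(cs[, 1], ct[, 1]), X3 = c(cs[, 2], ct[, 2]))
}

# Write a cohort to a temp file in the canonical single-SNP layout.
write_temp_cohort <- function(tab, sep = "\t") {
  path <- tempfile(fileext = ".tsv")
  write_cohort(tab, path, sep = sep)
  path
}
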