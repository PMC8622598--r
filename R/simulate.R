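#' Configuration of one case-control simulation cell
#'
#' Describes a single operating-characteristic experiment: a retrospective
#' case-control sample of size `n` with a diallelic marker in Hardy-Weinberg
#' proportions at the given minor-allele frequency, two covariates
#' (X2 ~ Bernoulli(0.5), a sex-like indicator; X3 ~ Uniform(0,1), an
#' age-like continuous variable) and disease risk
#' \deqn{\mathrm{logit}\,\Pr(D=1) = \alpha_1 + \alpha_2 X_2 + \alpha_3 X_3 + \beta\{z I(G=1) + I(G=2)\}}
#' where z is the generating genetic model's score. The default intercept
#' \eqn{\alpha_1 = -5} gives a rare-disease population from which cases are
#' ascertained retrospectively.
#'
#' @param n total sample size (cases + controls), at least 20.
#' @param maf minor-allele frequency in (0, 0.5].
#' @param alpha numeric length-3 vector \eqn{(\alpha_1,\alpha_2,\alpha_3)}:
#'   intercept, binary-covariate and continuous-covariate effects.
#' @param beta genetic effect on the logit scale (0 = null).
#' @param model generating genetic model: "REC", "ADD" or "DOM".
#' @param case_fraction proportion of cases (default 1/2, i.e. 1:1).
#' @param replicates number of Monte-Carlo replicates (>= 1).
#' @param seed master integer seed; per-replicate streams are derived from
#'   it deterministically.
#' @param nominal_levels significance thresholds for rejection-rate
#'   summaries, all in (0, 1) (a literal 0 is allowed and yields rate 0).
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n = 2000, maf = 0.3, alpha = c(-5, 0.25, 0.25),
                       beta = 0, model = c("ADD", "REC", "DOM"),
                       case_fraction = 0.5, replicates = 10000L,
                       seed = 1L, nominal_levels = c(0.05, 0.01)) {
  model <- match.arg(model)
  stopifnot(n >= 20, maf > 0, maf <= 0.5, length(alpha) == 3,
            all(is.finite(alpha)), is.finite(beta),
            case_fraction > 0, case_fraction < 1, replicates >= 1,
            all(nominal_levels >= 0), all(nominal_levels < 1))
  structure(list(n = as.integer(n), maf = maf, alpha = as.numeric(alpha),
                 beta = beta, model = model,
                 z = MODEL_SCORES[match(model, MODEL_LABELS)],
                 case_fraction = case_fraction,
                 replicates = as.integer(replicates),
                 seed = as.integer(seed),
                 nominal_levels = as.numeric(nominal_levels)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: n=%d (%.0f%% cases), MAF=%.2f, alpha=(%g, %g, %g), beta=%g (%s), %d replicates, seed=%d\n",
              x$n, 100 * x$case_fraction, x$maf, x$alpha[1], x$alpha[2],
              x$alpha[3], x$beta, x$model, x$replicates, x$seed))
  invisible(x)
}

# Raw retrospective sampler. Draws (X2, X3, G) from the population law and
# accepts candidates into the case stratum with probability f/f_max and the
# control stratum with (1-f)/(1-f_min) (envelope rejection sampling) --
# distributionally identical to thinning D ~ Bernoulli(f) until the quotas
# fill, but efficient at the rare-disease prevalence exp(alpha1) implies.
# Returns list(D, G, X) with cases first; X includes the intercept.
sample_case_control <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_case <- as.integer(round(config$n * config$case_fraction))
  n_ctrl <- config$n - n_case
  a <- config$alpha; b <- config$beta; z <- config$z; maf <- config$maf
  gprob <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
  geff <- c(0, z * b, b)
  eta_max <- a[1] + max(0, a[2]) + max(0, a[3]) + max(0, geff)
  eta_min <- a[1] + min(0, a[2]) + min(0, a[3]) + min(0, geff)
  fmax <- expit(eta_max); fmin <- expit(eta_min)
  if (fmax <= 0) stop("case yield impossible under this configuration",
                      call. = FALSE)
  draw_stratum <- function(quota, want_case) {
    X2 <- numeric(0); X3 <- numeric(0); G <- numeric(0)
    # acceptance rate is bounded below by E f / fmax; start generous
    chunk <- max(512L, as.integer(ceiling(quota * 1.5)))
    tries <- 0L
    while (length(G) < quota) {
      tries <- tries + 1L
      if (tries > 1000L)
        stop("case-control quota not met after bounded draws; ",
             "configuration may make one stratum unreachable", call. = FALSE)
      x2 <- stats::rbinom(chunk, 1L, 0.5)
      x3 <- stats::runif(chunk)
      g <- sample.int(3L, chunk, replace = TRUE, prob = gprob) - 1L
      f <- expit(a[1] + a[2] * x2 + a[3] * x3 + geff[g + 1L])
      acc <- if (want_case) stats::runif(chunk) < f / fmax
             else stats::runif(chunk) < (1 - f) / (1 - fmin)
      X2 <- c(X2, x2[acc]); X3 <- c(X3, x3[acc]); G <- c(G, g[acc])
      if (length(G) < quota) {
        rate <- max(length(G) / (tries * chunk), 1e-3)
        chunk <- as.integer(min(2e6, ceiling((quota - length(G)) * 1.5 / rate)))
      }
    }
    list(X2 = X2[seq_len(quota)], X3 = X3[seq_len(quota)],
         G = G[seq_len(quota)])
  }
  cs <- draw_stratum(n_case, TRUE)
  ct <- draw_stratum(n_ctrl, FALSE)
  list(D = rep(c(1, 0), c(n_case, n_ctrl)),
       G = c(cs$G, ct$G),
       X = cbind(1, c(cs$X2, ct$X2), c(cs$X3, ct$X3)))
}

#' Generate one retrospective case-control cohort
#'
#' Draws a [cohort_table()] under the configured population model:
#' covariates X2 ~ Bernoulli(0.5) and X3 ~ Uniform(0,1), genotype in
#' Hardy-Weinberg proportions at the configured MAF independent of the
#' covariates, disease risk from the logistic model, and retrospective
#' ascertainment (rejection sampling until the case and control quotas are
#' met).
#'
#' @param config a [sim_config()].
#' @param seed integer seed for this draw; defaults to `config$seed`.
#' @return A validated [cohort_table()] with covariate columns `X2`, `X3`.
#' @export
simulate_cohort <- function(config, seed = config$seed) {
  raw <- sample_case_control(config, seed = seed)
  cohort_table(raw$D, raw$G,
               covariates = cbind(X2 = raw$X[, 2], X3 = raw$X[, 3]))
}

SIM_TESTS <- c("CMAX3", "LRT", "S0", "S05", "S1", "OMAX3")

# One replicate -> named p-value vector over SIM_TESTS (NA where degenerate).
replicate_pvalues <- function(config, seed, tests = SIM_TESTS) {
  raw <- sample_case_control(config, seed = seed)
  p <- stats::setNames(rep(NA_real_, length(SIM_TESTS)), SIM_TESTS)
  need_core <- any(c("CMAX3", "S0", "S05", "S1") %in% tests)
  fit <- irls_logistic(raw$X, raw$D)
  if (need_core) {
    core <- cmax3_core(raw$D, raw$G, raw$X, fitted = fit$fitted)
    p["CMAX3"] <- core$p_value
    p[c("S0", "S05", "S1")] <- core$p_model
  }
  if ("LRT" %in% tests) {
    tab <- structure(list(phenotype = raw$D, genotype = raw$G,
                          covariates = raw$X, n = length(raw$D),
                          L = ncol(raw$X)), class = "cohort_table")
    nf <- structure(list(alpha_hat = fit$coefficients, fitted = fit$fitted,
                         loglik = fit$loglik, converged = TRUE,
                         iterations = fit$iterations), class = "null_fit")
    lr <- tryCatch(suppressWarnings(lrt_test(tab, nf)),
                   error = function(e) NULL)
    if (!is.null(lr)) p["LRT"] <- lr$p_value
  }
  if ("OMAX3" %in% tests) {
    oc <- cmax3_core(raw$D, raw$G, matrix(1, length(raw$D), 1))
    p["OMAX3"] <- oc$p_value
  }
  p[tests]
}

#' Empirical rejection rates under one simulation configuration
#'
#' Runs `config$replicates` independent replicates (each with a
#' deterministically derived seed, so results are bit-reproducible and
#' order-independent), applies the requested tests to each replicate, and
#' tabulates the fraction of p-values below each nominal level. With
#' `beta = 0` this estimates type I error; with `beta > 0`, power.
#' Degenerate (`NA`) test results are counted separately and excluded from
#' the denominator.
#'
#' @param config a [sim_config()].
#' @param tests subset of `c("CMAX3", "LRT", "S0", "S05", "S1", "OMAX3")`
#'   (S0/S05/S1 are the single-model score tests; OMAX3 the covariate-free
#'   comparator). Default: all but OMAX3.
#' @param keep_pvalues keep the replicate-by-test p-value matrix as
#'   attribute `"pvalues"` (default `TRUE`; used by calibration checks).
#' @return An object of class `operating_characteristics`: data frame with
#'   columns `test`, `level`, `rate`, `lower`, `upper` (95 percent
#'   Clopper-Pearson interval), `n_used`, `n_na`; the configuration is
#'   attached as attribute `"config"`.
#' @export
rejection_rates <- function(config, tests = setdiff(SIM_TESTS, "OMAX3"),
                            keep_pvalues = TRUE) {
  tests <- match.arg(tests, SIM_TESTS, several.ok = TRUE)
  B <- config$replicates
  P <- matrix(NA_real_, B, length(tests), dimnames = list(NULL, tests))
  for (b in seq_len(B))
    P[b, ] <- replicate_pvalues(config, derive_seed(config$seed, b), tests)
  rows <- list()
  for (te in tests) for (lv in config$nominal_levels) {
    ok <- !is.na(P[, te])
    k <- sum(P[ok, te] < lv)
    m <- sum(ok)
    ci <- if (m > 0) stats::binom.test(k, m)$conf.int else c(NA_real_, NA_real_)
    rows[[length(rows) + 1L]] <-
      data.frame(test = te, level = lv, rate = if (m > 0) k / m else NA_real_,
                 lower = ci[1], upper = ci[2], n_used = m, n_na = B - m)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("operating_characteristics", class(out))
  attr(out, "config") <- config
  if (keep_pvalues) attr(out, "pvalues") <- P
  out
}

#' @export
print.operating_characteristics <- function(x, ...) {
  cfg <- attr(x, "config")
  if (!is.null(cfg)) print(cfg)
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Power grid over several simulation configurations
#'
#' Convenience wrapper running [rejection_rates()] for each configuration
#' and stacking the results with the cell descriptors (generating model,
#' MAF, covariate effects, beta, n) as columns -- the layout of a
#' power-study table stratified by generating model.
#'
#' @param configs list of [sim_config()] objects (power cells have
#'   `beta > 0`; `beta = 0` cells reduce to type-I-error rows).
#' @param tests as in [rejection_rates()].
#' @return A data frame of class `operating_characteristics` with one row
#'   per (cell, test, level).
#' @export
power_table <- function(configs, tests = setdiff(SIM_TESTS, "OMAX3")) {
  stopifnot(length(configs) >= 1)
  rows <- lapply(configs, function(cfg) {
    oc <- rejection_rates(cfg, tests = tests, keep_pvalues = FALSE)
    cbind(data.frame(model = cfg$model, n = cfg$n, maf = cfg$maf,
                     alpha2 = cfg$alpha[2], alpha3 = cfg$alpha[3],
                     beta = cfg$beta),
          as.data.frame(oc))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("operating_characteristics", class(out))
  out
}

# Parse a key=value simulation config file (lines like "maf=0.3",
# "alpha=-5,1,0.5", "nominal_levels=0.05,0.01"; '#' comments allowed).
read_sim_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed config line: ", lines[which(bad)[1]],
                     call. = FALSE)
  vals <- stats::setNames(lapply(kv, function(x) trimws(x[2])),
                          vapply(kv, function(x) trimws(x[1]), ""))
  num <- function(key, default) {
    if (is.null(vals[[key]])) default
    else as.numeric(strsplit(vals[[key]], ",")[[1]])
  }
  chr <- function(key, default) {
    if (is.null(vals[[key]])) default else vals[[key]]
  }
  sim_config(n = num("n", 2000), maf = num("maf", 0.3),
             alpha = num("alpha", c(-5, 0.25, 0.25)),
             beta = num("beta", 0), model = chr("model", "ADD"),
             case_fraction = num("case_fraction", 0.5),
             replicates = num("replicates", 10000),
             seed = num("seed", 1),
             nominal_levels = num("nominal_levels", c(0.05, 0.01)))
}
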