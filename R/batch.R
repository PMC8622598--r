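#' Single-SNP analysis of a delimited subject-level file
#'
#' Reads a file in the (phenotype, genotype, covariates...) layout, runs the
#' covariate-adjusted MAX3 test, the 2-df LRT and the three single-model
#' score tests, prints a report and returns the results. Results are
#' invariant to swapping the 0/1 case-control coding.
#'
#' @inheritParams read_cohort
#' @param quiet suppress the printed report.
#' @return A `max3_result` (see [cmax3_test()]), invisibly when printed.
#' @export
run_single <- function(path, sep = NULL, header = NA, quiet = FALSE) {
  tab <- read_cohort(path, sep = sep, header = header)
  res <- suppressWarnings(cmax3_test(tab))
  if (!quiet) print(res)
  invisible(res)
}

BATCH_COLUMNS <- c("snp", "cmax3_p", "lrt_p", "s_rec_p", "s_add_p",
                   "s_dom_p", "best_model", "note")

#' Batch screening of a genotype matrix
#'
#' Runs the covariate-adjusted MAX3 test (plus LRT and per-model score
#' tests) on every SNP of a subjects x SNPs genotype matrix against a shared
#' phenotype/covariate table. The covariate-only null model depends only on
#' the phenotype and covariates, so it is fitted once and reused for every
#' SNP; SNPs with missing genotypes fall back to a complete-case refit.
#' Per-SNP failures (monomorphic markers, separation) are recorded as `NA`
#' rows with a note and the run continues.
#'
#' @param geno_path path to the genotype matrix file: one header row of SNP
#'   identifiers, then one row per subject with entries 0/1/2 (NA allowed).
#' @param pheno_path path to the phenotype/covariate file: column 1 the 0/1
#'   phenotype, remaining columns covariates (same subject order as the
#'   genotype matrix).
#' @param out_path optional path; when given, the result table is written
#'   there as tab-separated text (byte-identical across runs for fixed
#'   inputs).
#' @param sep,header passed to the readers (auto-detected by default).
#' @param digits significant digits for the written p-values (default 2,
#'   scientific notation; use `NA` for full precision).
#' @return A data frame with columns
#'   `snp, cmax3_p, lrt_p, s_rec_p, s_add_p, s_dom_p, best_model, note`,
#'   ordered by `cmax3_p` ascending (ties and `NA`s keep input order).
#' @export
run_batch <- function(geno_path, pheno_path, out_path = NULL,
                      sep = NULL, header = NA, digits = 2) {
  ph <- utils::read.table(pheno_path,
                          sep = if (is.null(sep)) detect_sep(readLines(pheno_path, n = 1)) else sep,
                          header = if (is.na(header)) {
                            l1 <- readLines(pheno_path, n = 1)
                            s <- if (is.null(sep)) detect_sep(l1) else sep
                            toks <- strsplit(trimws(l1), if (s == "") "[[:space:]]+" else s)[[1]]
                            all(is.na(suppressWarnings(as.numeric(toks))))
                          } else header)
  gl1 <- readLines(geno_path, n = 1)
  gsep <- if (is.null(sep)) detect_sep(gl1) else sep
  geno <- utils::read.table(geno_path, sep = gsep, header = TRUE,
                            check.names = FALSE)
  if (nrow(geno) != nrow(ph))
    stop(sprintf("subject count mismatch: %d genotype rows vs %d phenotype rows",
                 nrow(geno), nrow(ph)), call. = FALSE)
  D <- as.numeric(ph[[1]])
  cov <- if (ncol(ph) > 1) as.matrix(ph[, -1, drop = FALSE]) else NULL
  cc0 <- stats::complete.cases(cbind(D, cov))
  base_tab <- cohort_table(D[cc0], rep(0, sum(cc0)),
                           covariates = if (is.null(cov)) NULL else cov[cc0, , drop = FALSE],
                           validate = FALSE)
  base_fit <- fit_null(base_tab)
  snps <- colnames(geno)
  run_one <- function(j) {
    G <- as.numeric(geno[[j]])
    keep <- cc0 & !is.na(G)
    res <- tryCatch({
      tab <- cohort_table(D[keep], G[keep],
                          covariates = if (is.null(cov)) NULL else cov[keep, , drop = FALSE])
      fit <- if (identical(keep, cc0)) base_fit else fit_null(tab)
      suppressWarnings(cmax3_test(tab, fit = fit))
    }, error = function(e) e)
    if (inherits(res, "error"))
      return(data.frame(snp = snps[j], cmax3_p = NA_real_, lrt_p = NA_real_,
                        s_rec_p = NA_real_, s_add_p = NA_real_,
                        s_dom_p = NA_real_, best_model = NA_character_,
                        note = conditionMessage(res)))
    data.frame(snp = snps[j], cmax3_p = res$p_value, lrt_p = res$lrt_p,
               s_rec_p = res$per_model$REC$p_two_sided,
               s_add_p = res$per_model$ADD$p_two_sided,
               s_dom_p = res$per_model$DOM$p_two_sided,
               best_model = res$best_model,
               note = if (is.na(res$na_reason)) "" else res$na_reason)
  }
  out <- if (length(snps)) do.call(rbind, lapply(seq_along(snps), run_one))
         else stats::setNames(as.data.frame(matrix(nrow = 0, ncol = 8)),
                              BATCH_COLUMNS)
  # stable sort: CMAX3 p ascending, NAs last, ties by input position
  if (nrow(out)) out <- out[order(out$cmax3_p, seq_len(nrow(out)),
                                  na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(out_path)) {
    fmt <- out
    pcols <- c("cmax3_p", "lrt_p", "s_rec_p", "s_add_p", "s_dom_p")
    if (!is.na(digits) && nrow(fmt))
      for (cn in pcols)
        fmt[[cn]] <- ifelse(is.na(out[[cn]]), "NA",
                            formatC(out[[cn]], digits = digits - 1,
                                    format = "e"))
    utils::write.table(fmt, out_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  out
}
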