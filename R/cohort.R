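#' Subject-level case-control cohort
#'
#' A `cohort_table` bundles the three ingredients of a single-marker
#' case-control analysis: a binary phenotype \eqn{D_i} (1 = case,
#' 0 = control), a risk-allele count \eqn{G_i \in \{0,1,2\}}, and a covariate
#' matrix \eqn{X} whose first column is identically 1 (the intercept).
#' All downstream statistics (score tests, MAX3, LRT) consume this container.
#'
#' @param phenotype integer/numeric vector of 0/1 disease indicators.
#' @param genotype integer/numeric vector of risk-allele counts in {0,1,2}.
#' @param covariates optional numeric matrix or data frame of covariates,
#'   one row per subject, \emph{without} an intercept column: an all-ones
#'   intercept is always prepended. `NULL` means intercept only.
#' @param validate if `TRUE` (default) any ERROR-severity finding aborts
#'   construction. Set to `FALSE` to build an object for inspection with
#'   [validate_cohort()].
#'
#' @return An object of class `cohort_table`: a list with elements
#'   `phenotype`, `genotype`, `covariates` (n x L matrix including the
#'   intercept), `n` and `L`.
#' @seealso [read_cohort()], [validate_cohort()], [cmax3_test()]
#' @examples
#' tab <- cohort_table(c(1, 1, 0, 0), c(2, 1, 0, 1),
#'                     covariates = cbind(sex = c(1, 0, 1, 0)))
#' tab$L  # 2: intercept + sex
#' @export
cohort_table <- function(phenotype, genotype, covariates = NULL,
                         validate = TRUE) {
  phenotype <- as.numeric(phenotype)
  genotype <- as.numeric(genotype)
  n <- length(phenotype)
  if (is.null(covariates)) {
    X <- matrix(1, nrow = n, ncol = 1)
    colnames(X) <- "(Intercept)"
  } else {
    X <- as.matrix(covariates)
    storage.mode(X) <- "double"
    if (is.null(colnames(X))) colnames(X) <- paste0("X", seq_len(ncol(X)) + 1L)
    X <- cbind("(Intercept)" = 1, X)
  }
  obj <- structure(
    list(phenotype = phenotype, genotype = genotype, covariates = X,
         n = n, L = ncol(X)),
    class = "cohort_table")
  if (validate) {
    f <- validate_cohort(obj)
    bad <- f$severity == "ERROR"
    if (any(bad)) stop("invalid cohort_table: ",
                       paste(f$message[bad], collapse = "; "), call. = FALSE)
  }
  obj
}

#' Validate a cohort table
#'
#' Checks every structural invariant of the data model and returns
#' machine-readable findings rather than raising conditions. ERROR findings
#' mean downstream statistics are undefined; WARNING findings (monomorphic
#' marker, empty genotype class) mean some statistics may degenerate to `NA`.
#'
#' `validate_cohort` is pure: repeated calls on the same object return
#' identical findings.
#'
#' @param table a `cohort_table` (possibly built with `validate = FALSE`).
#' @return A data frame with columns `severity` ("ERROR"/"WARNING"), `code`
#'   and `message`; zero rows for a fully valid table.
#' @export
validate_cohort <- function(table) {
  f <- list()
  add <- function(severity, code, message)
    f[[length(f) + 1L]] <<- data.frame(severity = severity, code = code,
                                       message = message)
  D <- table$phenotype; G <- table$genotype; X <- table$covariates
  n <- table$n
  if (anyNA(D) || !all(D %in% c(0, 1)))
    add("ERROR", "phenotype_domain", "phenotype must contain only 0/1")
  else if (length(unique(D)) < 2L)
    add("ERROR", "phenotype_degenerate",
        "phenotype has a single class; need both cases and controls")
  if (anyNA(G) || !all(G %in% c(0, 1, 2)))
    add("ERROR", "genotype_domain", "genotype must contain only 0/1/2")
  else {
    counts <- tabulate(factor(G, levels = 0:2), nbins = 3L)
    if (sum(counts > 0L) == 1L)
      add("WARNING", "monomorphic", "genotype is monomorphic")
    else if (any(counts == 0L))
      add("WARNING", "empty_genotype_class",
          paste0("no subjects with genotype ",
                 paste(which(counts == 0L) - 1L, collapse = "/")))
  }
  if (length(G) != n || nrow(X) != n)
    add("ERROR", "length_mismatch",
        "phenotype, genotype and covariates must have the same number of rows")
  if (anyNA(X))
    add("ERROR", "covariate_missing", "covariates contain missing values")
  else {
    if (any(X[, 1L] != 1))
      add("ERROR", "intercept", "first covariate column must be all ones")
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      drop_col <- qrX$pivot[seq.int(qrX$rank + 1L, ncol(X))]
      add("ERROR", "collinear",
          paste0("covariates are rank deficient; offending column(s): ",
                 paste(colnames(X)[drop_col], collapse = ", ")))
    }
  }
  if (length(f) == 0L)
    data.frame(severity = character(), code = character(),
               message = character())
  else
    do.call(rbind, f)
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("cohort_table: %d subjects (%d cases / %d controls), %d covariate column(s) incl. intercept\n",
              x$n, sum(x$phenotype == 1), sum(x$phenotype == 0), x$L))
  cnt <- tabulate(factor(x$genotype, levels = 0:2), nbins = 3L)
  cat(sprintf("genotype counts: G=0: %d, G=1: %d, G=2: %d\n",
              cnt[1], cnt[2], cnt[3]))
  invisible(x)
}

# Detect delimiter from the first line: comma, tab, then whitespace.
detect_sep <- function(line) {
  if (grepl(",", line)) "," else if (grepl("\t", line)) "\t" else ""
}

#' Read a subject-level table from delimited text
#'
#' Expects the layout used by single-SNP analysis: column 1 the phenotype
#' (1 = case, 0 = control), column 2 the genotype (0/1/2 risk-allele count),
#' remaining columns the covariates. An intercept column is prepended
#' automatically. Rows with missing values in any used column are dropped
#' (complete-case) with a message reporting the count.
#'
#' @param path path to a delimited text file.
#' @param sep field separator; `NULL` (default) auto-detects comma, tab or
#'   whitespace from the first line.
#' @param header `NA` (default) auto-detects a header row by a non-numeric
#'   first line; or `TRUE`/`FALSE`.
#' @return A validated [cohort_table()].
#' @export
read_cohort <- function(path, sep = NULL, header = NA) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("empty file: ", path, call. = FALSE)
  if (is.null(sep)) sep <- detect_sep(first)
  if (is.na(header)) {
    # a header row is all names; a data row with a stray token is an error
    toks <- strsplit(trimws(first), if (sep == "") "[[:space:]]+" else sep)[[1]]
    header <- all(is.na(suppressWarnings(as.numeric(toks))))
  }
  df <- utils::read.table(path, sep = sep, header = header,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop("need at least 2 columns (phenotype, genotype)", call. = FALSE)
  for (j in seq_len(ncol(df))) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(v) & !is.na(df[[j]]) & df[[j]] != "NA")
    if (length(bad))
      stop(sprintf("malformed numeric in column %d ('%s'), data row %d",
                   j, names(df)[j], bad[1]), call. = FALSE)
    df[[j]] <- v
  }
  cc <- stats::complete.cases(df)
  if (any(!cc)) {
    message(sum(!cc), " row(s) dropped for missing values (complete-case)")
    df <- df[cc, , drop = FALSE]
  }
  cov <- if (ncol(df) > 2L) as.matrix(df[, -(1:2), drop = FALSE]) else NULL
  cohort_table(df[[1]], df[[2]], covariates = cov)
}

#' Write a cohort table as delimited text
#'
#' Inverse of [read_cohort()]: writes phenotype, genotype and the covariate
#' columns (the intercept column is omitted, since reading re-creates it).
#'
#' @param table a `cohort_table`.
#' @param path output file path.
#' @param sep field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(table, path, sep = "\t") {
  cov <- table$covariates[, -1L, drop = FALSE]
  df <- data.frame(phenotype = table$phenotype, genotype = table$genotype)
  if (ncol(cov)) df <- cbind(df, as.data.frame(cov))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Genetic model registry: label <-> score pairing and heterozygote
# penetrance rule f1 as a function of (f0, f2).
genetic_models <- function() {
  list(
    REC = list(label = "REC", z = 0,
               penetrance_rule = function(f0, f2) f0),
    ADD = list(label = "ADD", z = 0.5,
               penetrance_rule = function(f0, f2) (f0 + f2) / 2),
    DOM = list(label = "DOM", z = 1,
               penetrance_rule = function(f0, f2) f2)
  )
}
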