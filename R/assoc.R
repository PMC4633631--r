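#' Per-SNP logistic-regression association scan
#'
#' Fits one logistic regression per SNP with additive minor-allele coding
#' (0/1/2) and optional covariates, reporting the Wald test per SNP and the
#' cohort genomic-inflation factor. The minor allele is determined
#' cohort-wide before regression, so effects are log-odds per minor allele.
#' Missing genotypes are dropped casewise. SNPs whose fit does not converge,
#' separates, or is constant are flagged with `NA` statistics rather than
#' aborting the scan.
#'
#' @param geno A [genotype_data()] object (post-QC).
#' @param case_status Binary vector (1 = case) aligned to samples.
#' @param covariates Numeric matrix (n x c) of covariates (e.g. sex and the
#'   top 10 PCs), or `NULL`.
#' @return A list of class `assoc_result` with a data frame `table` (snp,
#'   chr, bp, a1, beta, se, chisq, p, flag) and `lambda_gc`.
#' @export
gwas_logistic <- function(geno, case_status, covariates = NULL) {
  stopifnot(inherits(geno, "genotype_data"))
  y <- as.numeric(case_status)
  if (!all(y %in% c(0, 1))) stop("case_status must be binary 0/1",
                                 call. = FALSE)
  dos <- geno$dosage
  n <- nrow(dos); m <- ncol(dos)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == n)
  }

  f <- colMeans(dos, na.rm = TRUE) / 2
  flip <- f > 0.5                        # orient to the minor allele
  beta <- se <- chisq <- p <- rep(NA_real_, m)
  flag <- character(m)

  for (j in seq_len(m)) {
    g <- dos[, j]
    if (flip[j]) g <- 2L - g
    ok <- !is.na(g)
    if (!is.null(covariates)) ok <- ok & stats::complete.cases(covariates)
    gg <- g[ok]
    if (length(unique(gg)) < 2L) { flag[j] <- "constant"; next }
    X <- if (is.null(covariates)) cbind(1, gg)
         else cbind(1, covariates[ok, , drop = FALSE], gg)
    fit <- tryCatch(
      suppressWarnings(stats::glm.fit(X, y[ok],
                                      family = stats::binomial())),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) { flag[j] <- "nonconverged"; next }
    cf <- fit$coefficients
    b <- cf[length(cf)]
    if (abs(b) > 15) { flag[j] <- "separated"; next }
    R <- qr.R(fit$qr)
    V <- tryCatch(chol2inv(R), error = function(e) NULL)
    if (is.null(V)) { flag[j] <- "singular"; next }
    s <- sqrt(V[length(cf), length(cf)])
    beta[j] <- b; se[j] <- s
    chisq[j] <- (b / s)^2
    p[j] <- stats::pchisq(chisq[j], 1, lower.tail = FALSE)
  }

  a1_minor <- ifelse(flip, geno$snp_map$a2, geno$snp_map$a1)
  tab <- data.frame(snp = geno$snp_map$id, chr = geno$snp_map$chr,
                    bp = geno$snp_map$bp, a1 = a1_minor,
                    beta = beta, se = se, chisq = chisq, p = p,
                    flag = flag, stringsAsFactors = FALSE)
  structure(list(table = tab,
                 lambda_gc = lambda_gc(chisq[!is.na(chisq)])),
            class = "assoc_result")
}

#' Genomic-inflation factor
#'
#' `lambda = median(chisq) / qchisq(0.5, 1)`: the ratio of the median
#' association chi-square to the theoretical median of the 1-df chi-square
#' distribution (0.4549...). Values above ~1.05 indicate residual
#' stratification or confounding.
#'
#' @param chi_squares Vector of 1-df chi-square statistics.
#' @return The inflation factor lambda.
#' @export
lambda_gc <- function(chi_squares) {
  if (length(chi_squares) == 0) stop("no chi-square statistics supplied",
                                     call. = FALSE)
  stats::median(chi_squares) / stats::qchisq(0.5, df = 1)
}

#' Write association results in summary-statistic TSV form
#'
#' Columns: SNP, CHR, BP, A1, BETA, SE, CHISQ, P.
#'
#' @param assoc An [gwas_logistic()] result.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_assoc <- function(assoc, path) {
  stopifnot(inherits(assoc, "assoc_result"))
  tab <- assoc$table
  out <- data.frame(SNP = tab$snp, CHR = tab$chr, BP = tab$bp, A1 = tab$a1,
                    BETA = tab$beta, SE = tab$se, CHISQ = tab$chisq,
                    P = tab$p)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
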