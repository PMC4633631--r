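#' QC thresholds
#'
#' Defaults follow standard GWAS practice for array data: SNP call rate
#' >= 95%, MAF >= 1%, Hardy-Weinberg exact p >= 0.01 (computed in controls),
#' case/control differential-missingness Fisher p >= 1e-3, sample call rate
#' >= 95%.
#'
#' @param snp_call_rate_min,maf_min,hwe_p_min,diff_missing_p_min,sample_call_rate_min
#'   Numeric thresholds in \[0, 1\].
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(snp_call_rate_min = 0.95,
                          maf_min = 0.01,
                          hwe_p_min = 0.01,
                          diff_missing_p_min = 1e-3,
                          sample_call_rate_min = 0.95) {
  th <- list(snp_call_rate_min = snp_call_rate_min, maf_min = maf_min,
             hwe_p_min = hwe_p_min, diff_missing_p_min = diff_missing_p_min,
             sample_call_rate_min = sample_call_rate_min)
  if (any(unlist(th) < 0 | unlist(th) > 1))
    stop("all QC thresholds must lie in [0, 1]", call. = FALSE)
  structure(th, class = "qc_thresholds")
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test: conditioning on the observed allele counts, the
#' p-value is the total probability of all heterozygote counts whose
#' conditional probability does not exceed that of the observed count.
#' Probabilities are evaluated in log space, so large samples are exact to
#' machine precision.
#'
#' @param hom1,het,hom2 Genotype counts (A1A1 homozygotes, heterozygotes,
#'   A2A2 homozygotes).
#' @return Two-sided exact p-value in (0, 1\].
#' @export
hwe_exact_test <- function(hom1, het, hom2) {
  if (any(c(hom1, het, hom2) < 0)) stop("counts must be non-negative",
                                        call. = FALSE)
  n <- hom1 + het + hom2
  if (n == 0) return(1)
  n1 <- 2L * hom1 + het            # A1 allele count
  n2 <- 2L * hom2 + het
  rare <- min(n1, n2)
  # attainable het counts share the parity of the rare allele count
  hets <- seq(rare %% 2L, rare, by = 2L)
  if (length(hets) == 1L) return(1)
  # log P(het = h | n, n1) up to a constant:
  #   log( n! / (hom1! het! hom2!) ) + h log 2
  h1 <- (n1 - hets) / 2
  h2 <- (n2 - hets) / 2
  logp <- hets * log(2) - lgamma(h1 + 1) - lgamma(hets + 1) - lgamma(h2 + 1)
  logp <- logp - max(logp)
  p <- exp(logp); p <- p / sum(p)
  obs <- p[match(het, hets)]
  min(1, sum(p[p <= obs * (1 + 1e-12)]))
}

#' Filter SNPs by call rate, MAF, HWE and differential missingness
#'
#' Filters are applied sequentially, with per-stage removal counts logged:
#' (1) call rate below threshold; (2) MAF below threshold; (3) Hardy-Weinberg
#' exact p below threshold, computed in controls only (females only for X
#' SNPs, since males are hemizygous); (4) two-sided Fisher exact test of
#' missing-call counts in cases versus controls.
#'
#' @param geno A [genotype_data()] object.
#' @param case_status Binary vector (1 = case) aligned to samples; may be
#'   `NULL`, in which case the HWE test uses everyone and the
#'   differential-missingness stage is skipped.
#' @param thresholds A [qc_thresholds()] object.
#' @return List with `geno` (filtered), `report` (a `qc_report`: per-stage
#'   removal counts, retained ids).
#' @export
filter_snps <- function(geno, case_status = NULL,
                        thresholds = qc_thresholds()) {
  stopifnot(inherits(geno, "genotype_data"))
  dos <- geno$dosage
  n <- nrow(dos)
  is_x <- geno$snp_map$region == "X"
  keep <- rep(TRUE, ncol(dos))
  removed <- c(call_rate = 0L, maf = 0L, hwe = 0L, diff_missing = 0L)

  call_rate <- colMeans(!is.na(dos))
  drop1 <- keep & call_rate < thresholds$snp_call_rate_min
  removed["call_rate"] <- sum(drop1)
  keep <- keep & !drop1

  f <- colMeans(dos, na.rm = TRUE) / 2
  maf <- pmin(f, 1 - f)
  maf[is.nan(maf)] <- 0
  drop2 <- keep & maf < thresholds$maf_min
  removed["maf"] <- sum(drop2)
  keep <- keep & !drop2

  hwe_rows <- if (is.null(case_status)) rep(TRUE, n) else case_status == 0L
  female <- !is.na(geno$sample_table$sex) & geno$sample_table$sex == 2L
  hwe_p <- rep(1, ncol(dos))
  for (j in which(keep)) {
    rows <- if (is_x[j]) hwe_rows & female else hwe_rows
    x <- dos[rows, j]
    x <- x[!is.na(x)]
    hwe_p[j] <- hwe_exact_test(sum(x == 2L), sum(x == 1L), sum(x == 0L))
  }
  drop3 <- keep & hwe_p < thresholds$hwe_p_min
  removed["hwe"] <- sum(drop3)
  keep <- keep & !drop3

  if (!is.null(case_status)) {
    miss <- is.na(dos)
    n_case <- sum(case_status == 1L)
    n_ctrl <- sum(case_status == 0L)
    miss_case <- colSums(miss[case_status == 1L, , drop = FALSE])
    miss_ctrl <- colSums(miss[case_status == 0L, , drop = FALSE])
    dm_p <- rep(1, ncol(dos))
    for (j in which(keep & (miss_case + miss_ctrl) > 0)) {
      tab <- matrix(c(miss_case[j], n_case - miss_case[j],
                      miss_ctrl[j], n_ctrl - miss_ctrl[j]), 2)
      dm_p[j] <- stats::fisher.test(tab)$p.value
    }
    drop4 <- keep & dm_p < thresholds$diff_missing_p_min
    removed["diff_missing"] <- sum(drop4)
    keep <- keep & !drop4
  }

  if (!any(keep)) stop("no SNPs survive QC", call. = FALSE)
  report <- structure(list(
    stage = "snp",
    n_input = ncol(dos),
    removed = removed,
    n_retained = sum(keep),
    retained_ids = geno$snp_map$id[keep]), class = "qc_report")
  list(geno = subset_geno(geno, j = which(keep)), report = report)
}

#' Filter samples by genotyping call rate
#'
#' @param geno A [genotype_data()] object.
#' @param thresholds A [qc_thresholds()] object.
#' @return List with `geno` (filtered) and `report` (a `qc_report`).
#' @export
filter_samples <- function(geno, thresholds = qc_thresholds()) {
  stopifnot(inherits(geno, "genotype_data"))
  cr <- rowMeans(!is.na(geno$dosage))
  keep <- cr >= thresholds$sample_call_rate_min
  if (!any(keep)) stop("no samples survive QC", call. = FALSE)
  report <- structure(list(
    stage = "sample",
    n_input = nrow(geno$dosage),
    removed = c(call_rate = sum(!keep)),
    n_retained = sum(keep),
    retained_ids = geno$sample_table$id[keep]), class = "qc_report")
  list(geno = subset_geno(geno, i = which(keep)), report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC report (%s level): %d -> %d retained\n", x$stage,
              x$n_input, x$n_retained))
  for (nm in names(x$removed))
    cat(sprintf("  removed by %s: %d\n", nm, x$removed[[nm]]))
  invisible(x)
}
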