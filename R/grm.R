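#' Partition SNPs into genomic regions
#'
#' Returns index subsets for (i) all autosomes, (ii) autosomes excluding the
#' extended MHC, (iii) the extended MHC only and (iv) chromosome X. The
#' extended MHC is chr6:26,500,000-34,000,000, both boundaries inclusive.
#'
#' @param snp_map SNP map data frame (columns `chr`, `bp`).
#' @param mhc_chr,mhc_start,mhc_end Region definition (1-based, inclusive).
#' @return List of integer index vectors: `auto`, `auto_exMHC`, `MHC`, `X`.
#' @export
partition_snps <- function(snp_map, mhc_chr = 6L, mhc_start = 26500000L,
                           mhc_end = 34000000L) {
  stopifnot(mhc_start < mhc_end)
  is_x <- snp_map$chr == 23L
  in_mhc <- snp_map$chr == mhc_chr & snp_map$bp >= mhc_start &
    snp_map$bp <= mhc_end
  list(auto = which(!is_x),
       auto_exMHC = which(!is_x & !in_mhc),
       MHC = which(in_mhc),
       X = which(is_x))
}

#' Build a genetic relationship matrix
#'
#' GCTA-style GRM on standardized dosages: entry (j,k) is the average over
#' SNPs, non-missing in both individuals, of
#' `(x_ij - 2 f_i)(x_ik - 2 f_i) / (2 f_i (1 - f_i))`, with allele
#' frequencies `f_i` estimated from the full analysis cohort. Monomorphic
#' SNPs are skipped. The diagonal uses the same cross-product formula as the
#' off-diagonal entries.
#'
#' @param geno A [genotype_data()] object.
#' @param snp_subset Integer/logical index or SNP ids selecting the SNPs
#'   (default: all autosomal SNPs).
#' @param region Label stored on the result (for bookkeeping).
#' @return A list of class `grm` with `K` (n x n), `M` (per-pair non-missing
#'   SNP counts), `ids`, `n_snps`, `region`.
#' @export
build_grm <- function(geno, snp_subset = NULL, region = "auto") {
  stopifnot(inherits(geno, "genotype_data"))
  if (is.null(snp_subset)) snp_subset <- which(geno$snp_map$region != "X")
  if (is.character(snp_subset))
    snp_subset <- match(snp_subset, geno$snp_map$id)
  X <- geno$dosage[, snp_subset, drop = FALSE]
  f <- colMeans(X, na.rm = TRUE) / 2
  poly <- !is.na(f) & f > 0 & f < 1
  if (!any(poly)) stop("all SNPs in the subset are monomorphic",
                       call. = FALSE)
  X <- X[, poly, drop = FALSE]
  f <- f[poly]
  Z <- sweep(sweep(X, 2, 2 * f), 2, sqrt(2 * f * (1 - f)), "/")
  obs <- !is.na(Z)
  Z[!obs] <- 0
  K_sum <- tcrossprod(Z)
  M <- tcrossprod(obs * 1)
  K <- K_sum / pmax(M, 1)
  ids <- geno$sample_table$id
  dimnames(K) <- list(ids, ids)
  structure(list(K = K, M = M, ids = ids, n_snps = ncol(Z),
                 region = region), class = "grm")
}

#' Build the X-chromosome GRM under full dosage compensation
#'
#' Females are standardized as on the autosomes. Males are hemizygous:
#' their 0/2 dosage is converted to a 0/1 allele count w and standardized as
#' `sqrt(2) * (w - f) / sqrt(f (1 - f))`, the full-dosage-compensation
#' coding in which one male allele carries the variance of two female
#' alleles. Allele frequency counts males once. Cross-sex entries use the
#' product of the sex-specific standardized scores.
#'
#' @param geno A [genotype_data()] object with sex known for every sample.
#' @return A `grm` object (region "X").
#' @export
build_grm_x <- function(geno) {
  stopifnot(inherits(geno, "genotype_data"))
  xs <- which(geno$snp_map$region == "X")
  if (length(xs) == 0) stop("no X-chromosome SNPs present", call. = FALSE)
  sex <- geno$sample_table$sex
  if (anyNA(sex)) stop("sex must be known for all samples", call. = FALSE)
  X <- geno$dosage[, xs, drop = FALSE]
  male <- sex == 1L
  W <- X
  W[male, ] <- W[male, , drop = FALSE] / 2      # male allele count 0/1
  a1 <- colSums(W, na.rm = TRUE)
  ntot <- colSums((!is.na(W)) * ifelse(male, 1, 2))
  f <- a1 / ntot
  poly <- !is.na(f) & f > 0 & f < 1
  if (!any(poly)) stop("all X SNPs are monomorphic", call. = FALSE)
  W <- W[, poly, drop = FALSE]
  f <- f[poly]
  Z <- matrix(0, nrow(W), ncol(W))
  Z[!male, ] <- sweep(sweep(W[!male, , drop = FALSE], 2, 2 * f),
                      2, sqrt(2 * f * (1 - f)), "/")
  Z[male, ] <- sqrt(2) * sweep(sweep(W[male, , drop = FALSE], 2, f),
                               2, sqrt(f * (1 - f)), "/")
  obs <- !is.na(W)
  Z[!obs] <- 0
  K <- tcrossprod(Z) / pmax(tcrossprod(obs * 1), 1)
  ids <- geno$sample_table$id
  dimnames(K) <- list(ids, ids)
  structure(list(K = K, M = tcrossprod(obs * 1), ids = ids,
                 n_snps = ncol(Z), region = "X"), class = "grm")
}

#' Prune related samples from a GRM
#'
#' Greedy maximum-retention pruning: while any off-diagonal entry exceeds
#' the threshold, remove the individual involved in the most over-threshold
#' pairs (ties broken by lower genotyping call rate, then lexicographic id).
#' Removing the hub of a relatedness chain retains its neighbours, so e.g.
#' in a chain A-B, B-C only B is removed.
#'
#' @param grm A [build_grm()] result.
#' @param threshold Relatedness cutoff on the GRM scale (default 0.05).
#' @param call_rate Optional per-sample call rates for tie-breaking.
#' @return Character vector of retained sample ids.
#' @export
prune_related <- function(grm, threshold = 0.05, call_rate = NULL) {
  stopifnot(inherits(grm, "grm"))
  K <- grm$K
  ids <- grm$ids
  n <- length(ids)
  if (is.null(call_rate)) call_rate <- rep(1, n)
  adj <- K > threshold
  diag(adj) <- FALSE
  active <- rep(TRUE, n)
  repeat {
    deg <- rowSums(adj[, active, drop = FALSE]) * active
    if (max(deg) == 0) break
    cand <- which(deg == max(deg))
    cand <- cand[order(call_rate[cand], ids[cand])]
    drop_i <- cand[1]
    active[drop_i] <- FALSE
    adj[drop_i, ] <- FALSE
    adj[, drop_i] <- FALSE
  }
  ids[active]
}

#' Write a GRM as GCTA-compatible text
#'
#' Emits `<prefix>.grm.gz` (gzipped triplets: index1 index2 count value,
#' lower triangle including the diagonal) and `<prefix>.grm.id`.
#'
#' @param grm A `grm` object.
#' @param prefix Output path prefix.
#' @return Invisibly, the two paths.
#' @export
write_grm <- function(grm, prefix) {
  stopifnot(inherits(grm, "grm"))
  n <- length(grm$ids)
  i <- rep(seq_len(n), times = seq_len(n))
  i <- unlist(lapply(seq_len(n), function(r) rep(r, r)))
  j <- unlist(lapply(seq_len(n), function(r) seq_len(r)))
  lin <- cbind(i, j)
  tri <- data.frame(i = lin[, 1], j = lin[, 2],
                    m = grm$M[lin], k = grm$K[lin])
  gz <- gzfile(paste0(prefix, ".grm.gz"), "w")
  utils::write.table(tri, gz, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  close(gz)
  utils::write.table(data.frame(grm$ids, grm$ids),
                     paste0(prefix, ".grm.id"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(c(paste0(prefix, ".grm.gz"), paste0(prefix, ".grm.id")))
}
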