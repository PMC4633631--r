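#' LD-pruning specification
#'
#' Defaults mirror the common `--indep-pairwise 50 10 0.2` setting: a
#' sliding window of 50 SNPs, step of 10, and a pairwise r^2 ceiling of 0.2.
#'
#' @param window_snps,step_snps,r2_max Window size (SNPs), step (SNPs) and
#'   maximum allowed pairwise r^2 within a window.
#' @return A list of class `prune_spec`.
#' @export
prune_spec <- function(window_snps = 50L, step_snps = 10L, r2_max = 0.2) {
  if (step_snps > window_snps) stop("step must not exceed window",
                                    call. = FALSE)
  structure(list(window_snps = as.integer(window_snps),
                 step_snps = as.integer(step_snps), r2_max = r2_max),
            class = "prune_spec")
}

#' Greedy windowed LD pruning
#'
#' Within each sliding window (per chromosome, SNPs ordered by position),
#' while any retained pair has dosage r^2 above `r2_max`, the member with
#' the lower MAF is dropped (ties: the later position). The window then
#' advances by `step_snps`. r^2 is the squared Pearson correlation of
#' dosages over pairwise-complete individuals (composite LD; phase is not
#' required).
#'
#' @param geno A [genotype_data()] object with SNPs ordered by chromosome
#'   and position.
#' @param spec A [prune_spec()] object.
#' @param max_snps If more SNPs survive than this, a deterministic
#'   every-kth subsample reduces the list to approximately `max_snps`
#'   (`NULL` = no cap).
#' @return Character vector of retained SNP ids.
#' @export
ld_prune <- function(geno, spec = prune_spec(), max_snps = NULL) {
  stopifnot(inherits(geno, "genotype_data"))
  map <- geno$snp_map
  ord <- order(map$chr, map$bp)
  if (any(diff(ord) < 0)) {
    geno <- subset_geno(geno, j = ord)
    map <- geno$snp_map
  }
  dos <- geno$dosage
  f <- colMeans(dos, na.rm = TRUE) / 2
  maf <- pmin(f, 1 - f)
  keep <- rep(TRUE, ncol(dos))

  for (chr in unique(map$chr)) {
    idx <- which(map$chr == chr)
    start <- 1L
    repeat {
      win <- idx[seq(start, min(start + spec$window_snps - 1L, length(idx)))]
      act <- win[keep[win]]
      if (length(act) > 1L) {
        r2 <- suppressWarnings(
          stats::cor(dos[, act, drop = FALSE],
                     use = "pairwise.complete.obs"))^2
        r2[is.na(r2)] <- 0
        diag(r2) <- 0
        while (TRUE) {
          mx <- which(r2 == max(r2), arr.ind = TRUE)[1, ]
          if (r2[mx[1], mx[2]] <= spec$r2_max) break
          a <- act[mx[1]]; b <- act[mx[2]]
          drop_snp <- if (maf[a] < maf[b]) a
            else if (maf[b] < maf[a]) b
            else max(a, b)               # tie: later position
          keep[drop_snp] <- FALSE
          di <- which(act == drop_snp)
          r2[di, ] <- 0; r2[, di] <- 0
        }
      }
      if (start + spec$window_snps - 1L >= length(idx)) break
      start <- start + spec$step_snps
    }
  }
  ids <- map$id[keep]
  if (!is.null(max_snps) && length(ids) > max_snps) {
    k <- ceiling(length(ids) / max_snps)
    ids <- ids[seq(1L, length(ids), by = k)]
  }
  ids
}

#' Principal components of standardized genotypes
#'
#' Singular value decomposition of the mean-imputed, standardized dosage
#' matrix over a pruned SNP set. Eigenvalues are those of the SNP-averaged
#' covariance (GRM scale). The sign of each component is fixed by making
#' the largest-magnitude SNP loading positive, so results are deterministic.
#'
#' @param geno A [genotype_data()] object.
#' @param pruned_ids SNP ids to use (typically from [ld_prune()]).
#' @param k Number of components.
#' @return A list of class `pca_result` with `scores` (n x k), `evals`, and
#'   the ids used.
#' @export
compute_pca <- function(geno, pruned_ids = NULL, k = 20L) {
  stopifnot(inherits(geno, "genotype_data"))
  j <- if (is.null(pruned_ids)) seq_len(ncol(geno$dosage))
       else match(pruned_ids, geno$snp_map$id)
  if (length(j) == 0) stop("pruned SNP set is empty", call. = FALSE)
  X <- geno$dosage[, j, drop = FALSE]
  f <- colMeans(X, na.rm = TRUE) / 2
  poly <- f > 0 & f < 1
  X <- X[, poly, drop = FALSE]; f <- f[poly]
  Z <- sweep(sweep(X, 2, 2 * f), 2, sqrt(2 * f * (1 - f)), "/")
  Z[is.na(Z)] <- 0
  if (k > min(dim(Z)) - 1L)
    stop("k exceeds the available rank", call. = FALSE)
  sv <- svd(Z, nu = k, nv = k)
  sgn <- vapply(seq_len(k), function(i) {
    v <- sv$v[, i]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  scores <- sweep(sv$u %*% diag(sv$d[seq_len(k)], k), 2, sgn, "*")
  rownames(scores) <- geno$sample_table$id
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(scores = scores,
                 evals = sv$d[seq_len(k)]^2 / ncol(Z),
                 snp_ids = colnames(X)),
            class = "pca_result")
}

#' Flag ancestry outliers on the top principal components
#'
#' A sample is flagged if any of its top `top_k` PC scores lies more than
#' `sd_threshold` standard deviations from that component's mean. The rule
#' can be iterated (recomputing mean/SD after each removal pass).
#'
#' @param pca A [compute_pca()] result.
#' @param sd_threshold SD multiple (default 6).
#' @param top_k Number of leading components examined (default 10).
#' @param iterations Number of flag-and-recompute passes (default 1).
#' @return Character vector of outlier sample ids (possibly empty).
#' @export
remove_pca_outliers <- function(pca, sd_threshold = 6.0, top_k = 10L,
                                iterations = 1L) {
  stopifnot(inherits(pca, "pca_result"))
  top_k <- min(top_k, ncol(pca$scores))
  S <- pca$scores[, seq_len(top_k), drop = FALSE]
  active <- rep(TRUE, nrow(S))
  for (it in seq_len(iterations)) {
    mu <- colMeans(S[active, , drop = FALSE])
    sd_ <- apply(S[active, , drop = FALSE], 2, stats::sd)
    sd_[sd_ == 0] <- Inf
    dev <- abs(sweep(sweep(S, 2, mu), 2, sd_, "/"))
    out <- active & apply(dev > sd_threshold, 1, any)
    if (!any(out)) break
    active <- active & !out
  }
  rownames(S)[!active]
}
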