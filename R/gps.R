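#' Convert association p-values to Z-scores
#'
#' Two-sided magnitude transform `Z = qnorm(1 - p/2)`: a SNP's Z-score is
#' large when its association p-value is small, regardless of effect
#' direction (direction is irrelevant to the max-min sharing statistic).
#' Z is clipped at the value corresponding to p = 1e-300 to avoid infinities.
#'
#' @param p_vector P-values in (0, 1].
#' @return Non-negative Z-scores of the same length.
#' @export
pvalues_to_zscores <- function(p_vector) {
  if (any(is.na(p_vector)) || any(p_vector <= 0) || any(p_vector > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  z <- stats::qnorm(pmax(p_vector, 1e-300) / 2, lower.tail = FALSE)
  pmin(z, stats::qnorm(5e-301, lower.tail = FALSE))
}

#' Genome-wide pairwise sharing statistic
#'
#' `gamma = max_j min(X_j, Y_j)`: the maximum over SNPs of the pairwise
#' minimum of the two traits' association Z-scores. If some SNP is strongly
#' associated with both traits, both of its Z-scores are large, so the
#' max-min is large; under the null of no shared SNPs the statistic stays
#' small. Threshold-free: no significance cutoff is chosen.
#'
#' @param X,Y SNP-aligned Z-score vectors of equal length.
#' @return The statistic gamma.
#' @export
gps_statistic <- function(X, Y) {
  if (length(X) != length(Y)) stop("X and Y must have equal length",
                                   call. = FALSE)
  if (length(X) == 0) stop("empty Z-score vectors", call. = FALSE)
  max(pmin(X, Y))
}

#' Analytic permutation p-value for the sharing statistic
#'
#' Under the permutation null (re-pairing Y against X uniformly at random),
#' `gamma_perm >= gamma` iff at least one of the `a = #{X_j >= gamma}`
#' large-X SNPs is paired with one of the `b = #{Y_j >= gamma}` large-Y
#' values. The probability that no such collision occurs is hypergeometric,
#' `C(n - a, b) / C(n, b)`, so `p = 1 - C(n - a, b) / C(n, b)`, evaluated in
#' log space. Exceedance is non-strict (ties at gamma count), which
#' guarantees `a, b >= 1` for a gamma attained by the data.
#'
#' @param gamma The observed statistic from [gps_statistic()].
#' @param X,Y The Z-score vectors gamma was computed from.
#' @return Permutation p-value in (0, 1].
#' @export
gps_pvalue_analytic <- function(gamma, X, Y) {
  if (length(X) != length(Y)) stop("X and Y must have equal length",
                                   call. = FALSE)
  n <- length(X)
  a <- sum(X >= gamma)
  b <- sum(Y >= gamma)
  if (a == 0 || b == 0)
    stop("internal error: gamma exceeds both maxima", call. = FALSE)
  if (b > n - a) return(1)
  # p = 1 - C(n-a, b)/C(n, b), in log space
  -expm1(lchoose(n - a, b) - lchoose(n, b))
}

#' Monte-Carlo permutation p-value for the sharing statistic
#'
#' Permutes the Y labels against X `n_perm` times and applies the standard
#' add-one estimator `p = (1 + #{gamma_perm >= gamma_obs}) / (n_perm + 1)`.
#' Provided as a cross-check of [gps_pvalue_analytic()].
#'
#' @param X,Y Z-score vectors.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed.
#' @return Permutation p-value.
#' @export
gps_pvalue_permutation <- function(X, Y, n_perm = 10000L, seed = 1L) {
  if (n_perm < 100) stop("n_perm must be at least 100", call. = FALSE)
  g_obs <- gps_statistic(X, Y)
  set.seed(seed)
  hits <- 0L
  n <- length(Y)
  for (b in seq_len(n_perm)) {
    if (max(pmin(X, Y[sample.int(n)])) >= g_obs) hits <- hits + 1L
  }
  (1 + hits) / (n_perm + 1)
}

#' Sharing test for every cohort pair
#'
#' Runs the genome-wide pairwise sharing test on each pair of association
#' result tables (a named list, typically 10 disease cohorts giving 45
#' pairs), on the common SNP universe, excluding extended-MHC SNPs by
#' default, and Bonferroni-adjusts the analytic p-values for the number of
#' pairs.
#'
#' @param assoc_list Named list of [gwas_logistic()] results (or data frames
#'   with columns `snp` and `p`; a `region` column enables MHC exclusion).
#' @param exclude_mhc Drop SNPs tagged "MHC" before testing (default TRUE).
#' @return A list with `pairs` (data frame: pair, gamma, a, b, n,
#'   p_analytic, p_adj) and `p_matrix` (symmetric adjusted-p matrix).
#' @export
gps_all_pairs <- function(assoc_list, exclude_mhc = TRUE) {
  stopifnot(is.list(assoc_list), length(assoc_list) >= 2,
            !is.null(names(assoc_list)))
  tabs <- lapply(assoc_list, function(a) {
    if (inherits(a, "assoc_result")) {
      data.frame(snp = a$table$snp, p = a$table$p,
                 chr = a$table$chr, bp = a$table$bp,
                 stringsAsFactors = FALSE)
    } else as.data.frame(a)
  })
  universe <- Reduce(intersect, lapply(tabs, function(t) t$snp))
  for (i in seq_along(tabs)) {
    extra <- setdiff(tabs[[i]]$snp, universe)
    if (length(extra) > 0)
      stop("mismatched SNP universes; e.g. cohort ", names(tabs)[i],
           " has ", length(extra), " unshared SNPs such as ", extra[1],
           call. = FALSE)
  }
  ref <- tabs[[1]][match(universe, tabs[[1]]$snp), ]
  keep <- rep(TRUE, length(universe))
  if (exclude_mhc && all(c("chr", "bp") %in% names(ref)))
    keep <- !(ref$chr == 6L & ref$bp >= 26500000L & ref$bp <= 34000000L)
  universe <- universe[keep]

  Z <- lapply(tabs, function(t) {
    p <- t$p[match(universe, t$snp)]
    ok <- !is.na(p)
    list(z = pvalues_to_zscores(p[ok]), ok = ok)
  })

  nm <- names(assoc_list)
  k <- length(nm)
  combos <- utils::combn(k, 2)
  n_pairs <- ncol(combos)
  rows <- vector("list", n_pairs)
  for (c_ in seq_len(n_pairs)) {
    i <- combos[1, c_]; j <- combos[2, c_]
    ok <- Z[[i]]$ok & Z[[j]]$ok
    X <- pvalues_to_zscores(tabs[[i]]$p[match(universe, tabs[[i]]$snp)][ok])
    Y <- pvalues_to_zscores(tabs[[j]]$p[match(universe, tabs[[j]]$snp)][ok])
    g <- gps_statistic(X, Y)
    a <- sum(X >= g); b <- sum(Y >= g)
    p <- gps_pvalue_analytic(g, X, Y)
    rows[[c_]] <- data.frame(
      pair = paste(nm[i], nm[j], sep = "-"), d1 = nm[i], d2 = nm[j],
      gamma = g, a = a, b = b, n = length(X), p_analytic = p,
      stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, rows)
  pairs$p_adj <- bonferroni_adjust(pairs$p_analytic, n_pairs)
  P <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  for (c_ in seq_len(n_pairs)) {
    i <- combos[1, c_]; j <- combos[2, c_]
    P[i, j] <- P[j, i] <- pairs$p_adj[c_]
  }
  list(pairs = pairs, p_matrix = P)
}
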