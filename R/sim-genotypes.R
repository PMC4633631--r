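#' Simulate biallelic genotypes
#'
#' Draws allele frequencies uniformly from `params$maf_range` and genotypes
#' binomially (2 trials per individual), independently across SNPs. When
#' `params$ld` is set, SNPs within each LD block are copies of the block's
#' first SNP with per-genotype resampling at `flip_prob`, giving a tunable
#' within-block r^2. An optional MHC block is laid out on chr6:26.5-34 Mb;
#' optional X-chromosome SNPs are appended with males hemizygous (dosage
#' 0/2).
#'
#' @param params A [sim_params()] object.
#' @return A [genotype_data()] object; the drawn allele frequencies are kept
#'   in `attr(, "true_freq")`.
#' @export
simulate_genotypes <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  n <- params$n_individuals
  m <- params$n_snps
  mx <- params$n_snps_x

  freq <- stats::runif(m + mx, params$maf_range[1], params$maf_range[2])

  dos <- matrix(stats::rbinom(n * m, 2L, rep(freq[seq_len(m)], each = n)),
                nrow = n, ncol = m)

  if (!is.null(params$ld)) {
    bs <- params$ld$block_size
    fp <- params$ld$flip_prob
    anchors <- seq(1L, m, by = bs)
    for (a in anchors) {
      members <- seq(a + 1L, min(a + bs - 1L, m))
      if (length(members) == 0 || a + 1L > m) next
      for (j in members) {
        freq[j] <- freq[a]
        flip <- stats::runif(n) < fp
        col <- dos[, a]
        col[flip] <- stats::rbinom(sum(flip), 2L, freq[a])
        dos[, j] <- col
      }
    }
  }

  sex <- rep(NA_integer_, n)
  if (mx > 0) {
    sex <- ifelse(stats::runif(n) < params$male_fraction, 1L, 2L)
    fx <- freq[m + seq_len(mx)]
    dx <- matrix(0L, n, mx)
    male <- sex == 1L
    if (any(male))
      dx[male, ] <- 2L * matrix(
        stats::rbinom(sum(male) * mx, 1L, rep(fx, each = sum(male))),
        ncol = mx)
    if (any(!male))
      dx[!male, ] <- matrix(
        stats::rbinom(sum(!male) * mx, 2L, rep(fx, each = sum(!male))),
        ncol = mx)
    dos <- cbind(dos, dx)
  }

  snp_map <- .layout_snp_map(m, mx, params$mhc_block)
  sample_table <- data.frame(
    id = sprintf("ind%05d", seq_len(n)),
    sex = sex,
    phenotype = NA_integer_,
    stringsAsFactors = FALSE)

  geno <- genotype_data(dos, snp_map, sample_table)
  attr(geno, "true_freq") <- freq
  geno
}

# Lay out SNP positions: autosomes before/after an optional chr6 MHC window,
# X SNPs at the end. Index order agrees with (chr, bp) order.
.layout_snp_map <- function(m, mx, mhc_block) {
  chr <- integer(m)
  bp <- integer(m)
  region <- rep("autosome", m)
  if (is.null(mhc_block)) {
    # spread evenly over chr 1..22
    chr <- as.integer(cut(seq_len(m), breaks = 22, labels = FALSE))
    for (c_ in unique(chr)) {
      k <- which(chr == c_)
      bp[k] <- seq_along(k) * 50000L
    }
  } else {
    a <- mhc_block$start; b <- mhc_block$end
    pre <- seq_len(a - 1L)
    post <- if (b < m) seq(b + 1L, m) else integer(0)
    if (length(pre)) {
      chr[pre] <- as.integer(cut(pre, breaks = 5, labels = FALSE))
      for (c_ in unique(chr[pre])) {
        k <- pre[chr[pre] == c_]
        bp[k] <- seq_along(k) * 50000L
      }
    }
    blk <- a:b
    chr[blk] <- 6L
    bp[blk] <- as.integer(round(seq(26500000, 34000000,
                                    length.out = length(blk))))
    region[blk] <- "MHC"
    if (length(post)) {
      chr[post] <- 6L + as.integer(cut(post, breaks = 16, labels = FALSE))
      for (c_ in unique(chr[post])) {
        k <- post[chr[post] == c_]
        bp[k] <- seq_along(k) * 50000L
      }
    }
  }
  map <- data.frame(
    id = sprintf("snp%06d", seq_len(m + mx)),
    chr = c(chr, rep(23L, mx)),
    bp = c(bp, if (mx > 0) seq_len(mx) * 50000L else integer(0)),
    a1 = "A", a2 = "B",
    region = c(region, rep("X", mx)),
    stringsAsFactors = FALSE)
  map
}

#' Simulate a pair of correlated liability-threshold traits
#'
#' Causal effects for the two traits are drawn from a bivariate normal with
#' correlation `rg_true`, on standardized dosages, so each causal SNP's
#' expected contribution to liability variance is MAF-independent. When an
#' MHC block with `var_share` s is configured, causal SNPs inside the block
#' jointly carry s of the genetic variance and the remaining causal SNPs
#' carry 1 - s. Residual liability is N(0, 1 - h2); an individual is a case
#' iff total liability exceeds `qnorm(1 - K)`. Causal SNPs are restricted to
#' the autosomes (including the MHC block).
#'
#' @param geno A complete (no missingness) [genotype_data()] object.
#' @param params A [sim_params()] object.
#' @param seed Optional seed; defaults to `params$seed + 1` so that genotype
#'   and phenotype draws are decoupled.
#' @return A list with `effects` (data frame: snp, index, beta1, beta2),
#'   `genetic1/2`, `liability1/2`, `threshold1/2`, and binary vectors
#'   `pheno1`, `pheno2` (1 = case).
#' @export
simulate_liability_pair <- function(geno, params, seed = params$seed + 1L) {
  stopifnot(inherits(geno, "genotype_data"), inherits(params, "sim_params"))
  if (anyNA(geno$dosage))
    stop("genotypes must be complete; inject missingness after phenotypes",
         call. = FALSE)
  set.seed(seed)
  auto <- which(geno$snp_map$region != "X")
  n_causal <- params$n_causal
  if (n_causal > length(auto))
    stop("n_causal exceeds the number of autosomal SNPs", call. = FALSE)

  blk <- if (!is.null(params$mhc_block))
    seq(params$mhc_block$start, params$mhc_block$end) else integer(0)
  share <- if (!is.null(params$mhc_block)) params$mhc_block$var_share else 0

  if (share > 0 && length(blk) > 0) {
    n_blk <- max(1L, min(length(blk),
                         as.integer(round(n_causal * length(blk) /
                                            length(auto)))))
    causal_blk <- sort(sample(blk, n_blk))
    causal_out <- sort(sample(setdiff(auto, blk), n_causal - n_blk))
    causal <- c(causal_blk, causal_out)
    w <- numeric(n_causal)
    w[seq_along(causal_blk)] <- share / length(causal_blk)
    w[seq_along(causal_out) + length(causal_blk)] <-
      (1 - share) / max(1L, length(causal_out))
  } else {
    causal <- sort(sample(auto, n_causal))
    w <- rep(1 / n_causal, n_causal)
  }

  X <- geno$dosage[, causal, drop = FALSE]
  f <- colMeans(X) / 2
  f <- pmin(pmax(f, 1e-6), 1 - 1e-6)
  Z <- sweep(sweep(X, 2, 2 * f), 2, sqrt(2 * f * (1 - f)), "/")

  rg <- params$rg_true
  u1 <- stats::rnorm(n_causal)
  u2 <- rg * u1 + sqrt(max(0, 1 - rg^2)) * stats::rnorm(n_causal)
  beta1 <- sqrt(params$h2_trait1 * w) * u1
  beta2 <- sqrt(params$h2_trait2 * w) * u2

  g1 <- drop(Z %*% beta1)
  g2 <- drop(Z %*% beta2)
  n <- nrow(X)
  l1 <- g1 + stats::rnorm(n, 0, sqrt(max(0, 1 - params$h2_trait1)))
  l2 <- g2 + stats::rnorm(n, 0, sqrt(max(0, 1 - params$h2_trait2)))
  t1 <- stats::qnorm(1 - params$prevalence1)
  t2 <- stats::qnorm(1 - params$prevalence2)

  list(effects = data.frame(snp = geno$snp_map$id[causal], index = causal,
                            beta1 = beta1, beta2 = beta2,
                            stringsAsFactors = FALSE),
       genetic1 = g1, genetic2 = g2,
       liability1 = l1, liability2 = l2,
       threshold1 = t1, threshold2 = t2,
       pheno1 = as.integer(l1 > t1),
       pheno2 = as.integer(l2 > t2))
}

#' Draw an ascertained case-control subset
#'
#' Randomly samples exactly `n_cases` cases and `n_controls` controls from a
#' binary phenotype vector and records the resulting sample case proportion
#' P, which downstream liability-scale transforms need.
#'
#' @param pheno Binary (0/1) phenotype vector.
#' @param n_cases,n_controls Requested counts.
#' @param seed Integer seed.
#' @return List with `idx` (sorted sample indices), `case_proportion` (P),
#'   and the realized counts.
#' @export
ascertain_case_control <- function(pheno, n_cases, n_controls, seed = 1L) {
  if (n_cases < 1 || n_controls < 1)
    stop("n_cases and n_controls must be positive", call. = FALSE)
  cases <- which(pheno == 1L)
  ctrls <- which(pheno == 0L)
  if (length(cases) < n_cases)
    stop(sprintf("insufficient cases: requested %d, available %d",
                 n_cases, length(cases)), call. = FALSE)
  if (length(ctrls) < n_controls)
    stop(sprintf("insufficient controls: requested %d, available %d",
                 n_controls, length(ctrls)), call. = FALSE)
  set.seed(seed)
  idx <- sort(c(sample(cases, n_cases), sample(ctrls, n_controls)))
  list(idx = idx,
       case_proportion = n_cases / (n_cases + n_controls),
       n_cases = n_cases, n_controls = n_controls)
}

#' Resolve comorbid individuals to a single disease cohort
#'
#' Individuals appearing in more than one case set are assigned to the
#' smaller cohort by post-assignment sample size (ties broken by
#' lexicographic disease code), so that every individual belongs to at most
#' one cohort. Assignment is iterated to a fixed point because moving
#' individuals changes cohort sizes.
#'
#' @param case_sets Named list of case-id vectors, one per disease.
#' @return Named list of disjoint case-id vectors.
#' @export
assign_comorbid_cases <- function(case_sets) {
  stopifnot(is.list(case_sets), !is.null(names(case_sets)))
  diseases <- names(case_sets)
  case_sets <- lapply(case_sets, unique)
  all_ids <- unique(unlist(case_sets))
  member <- lapply(all_ids, function(id)
    diseases[vapply(case_sets, function(s) id %in% s, logical(1))])
  assign <- vapply(member, `[[`, character(1), 1L)  # provisional
  for (iter in seq_len(100L)) {
    sizes <- table(factor(assign, levels = diseases))
    new_assign <- vapply(seq_along(all_ids), function(i) {
      cand <- member[[i]]
      if (length(cand) == 1L) return(cand)
      sz <- sizes[cand]
      cand[order(sz, cand)][1L]
    }, character(1))
    if (identical(new_assign, assign)) break
    assign <- new_assign
  }
  out <- lapply(diseases, function(d) sort(all_ids[assign == d]))
  names(out) <- diseases
  out
}
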