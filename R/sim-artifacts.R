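#' Inject QC-relevant artifacts into simulated genotypes
#'
#' Adds, in this order: (i) two-way (or k-way) population structure by
#' redrawing genotypes from subpopulation allele frequencies under a
#' Balding-Nichols Fst drift model, (ii) cryptic relatedness by replacing
#' individuals with Mendelian offspring of parent pairs, (iii)
#' Hardy-Weinberg violations by redrawing flagged SNPs with a strong
#' heterozygote deficit, (iv) random missingness per SNP and (v)
#' case/control differential missingness at flagged SNPs. Designed to
#' exercise every filter in the QC stage.
#'
#' @param geno A [genotype_data()] object.
#' @param missing_rate_per_snp Scalar rate applied to all SNPs, or a named
#'   vector (names = SNP ids) applied to those SNPs only.
#' @param differential_missing_snps SNP ids whose missingness depends on
#'   case status (`diff_rate_case` in cases vs `diff_rate_control` in
#'   controls).
#' @param hwe_violation_snps SNP ids redrawn with inbreeding-like excess
#'   homozygosity (F = 0.6).
#' @param n_related_pairs Number of parent pairs; for each, one unrelated
#'   individual is replaced by a Mendelian offspring of the pair.
#' @param n_subpops Number of subpopulations (1 = no structure).
#' @param fst Drift parameter of the Balding-Nichols model.
#' @param case_status Binary vector, required when
#'   `differential_missing_snps` is non-empty.
#' @param diff_rate_case,diff_rate_control Missingness rates at
#'   differentially missing SNPs.
#' @param seed Integer seed.
#' @return A `genotype_data` object; `attr(, "subpop")` records the
#'   subpopulation labels and `attr(, "related")` the
#'   (parent1, parent2, child) row indices.
#' @export
inject_artifacts <- function(geno,
                             missing_rate_per_snp = 0,
                             differential_missing_snps = character(0),
                             hwe_violation_snps = character(0),
                             n_related_pairs = 0L,
                             n_subpops = 1L,
                             fst = 0,
                             case_status = NULL,
                             diff_rate_case = 0.15,
                             diff_rate_control = 0.01,
                             seed = 1L) {
  stopifnot(inherits(geno, "genotype_data"))
  if (fst < 0 || fst > 1) stop("fst must lie in [0, 1]", call. = FALSE)
  set.seed(seed)
  dos <- geno$dosage
  n <- nrow(dos); m <- ncol(dos)
  snp_ids <- geno$snp_map$id
  is_x <- geno$snp_map$region == "X"

  subpop <- rep(1L, n)
  if (n_subpops > 1L) {
    subpop <- rep_len(seq_len(n_subpops), n)
    base_f <- pmin(pmax(colMeans(dos, na.rm = TRUE) / 2, 0.01), 0.99)
    for (k in seq_len(n_subpops)) {
      rows <- which(subpop == k)
      if (fst > 0) {
        fk <- stats::rbeta(m, base_f * (1 - fst) / fst,
                           (1 - base_f) * (1 - fst) / fst)
      } else {
        fk <- base_f
      }
      fk <- pmin(pmax(fk, 1e-4), 1 - 1e-4)
      if (fst > 0) {
        dos[rows, !is_x] <- matrix(
          stats::rbinom(length(rows) * sum(!is_x), 2L,
                        rep(fk[!is_x], each = length(rows))),
          nrow = length(rows))
      }
    }
  }

  related <- NULL
  if (n_related_pairs > 0L) {
    if (3L * n_related_pairs > n)
      stop("not enough individuals for the requested related pairs",
           call. = FALSE)
    perm <- sample(n, 3L * n_related_pairs)
    related <- data.frame(parent1 = perm[seq_len(n_related_pairs)],
                          parent2 = perm[n_related_pairs + seq_len(n_related_pairs)],
                          child = perm[2L * n_related_pairs + seq_len(n_related_pairs)])
    for (r in seq_len(n_related_pairs)) {
      p1 <- dos[related$parent1[r], ]
      p2 <- dos[related$parent2[r], ]
      a1 <- stats::rbinom(m, 1L, pmin(pmax(p1 / 2, 0), 1))
      a2 <- stats::rbinom(m, 1L, pmin(pmax(p2 / 2, 0), 1))
      dos[related$child[r], ] <- a1 + a2
    }
  }

  if (length(hwe_violation_snps) > 0) {
    j <- match(hwe_violation_snps, snp_ids)
    if (anyNA(j)) stop("unknown SNP id in hwe_violation_snps", call. = FALSE)
    Fin <- 0.6
    for (jj in j) {
      f <- pmin(pmax(mean(dos[, jj], na.rm = TRUE) / 2, 0.05), 0.95)
      p_hom2 <- (1 - f)^2 + Fin * f * (1 - f)
      p_het <- 2 * f * (1 - f) * (1 - Fin)
      dos[, jj] <- sample(c(0L, 1L, 2L), n, replace = TRUE,
                          prob = c(p_hom2, p_het, 1 - p_hom2 - p_het))
    }
  }

  if (length(missing_rate_per_snp) == 1L && is.null(names(missing_rate_per_snp))) {
    if (missing_rate_per_snp > 0) {
      miss <- matrix(stats::runif(n * m) < missing_rate_per_snp, n, m)
      dos[miss] <- NA_integer_
    }
  } else {
    j <- match(names(missing_rate_per_snp), snp_ids)
    if (anyNA(j)) stop("unknown SNP id in missing_rate_per_snp", call. = FALSE)
    for (k in seq_along(j)) {
      miss <- stats::runif(n) < missing_rate_per_snp[k]
      dos[miss, j[k]] <- NA_integer_
    }
  }

  if (length(differential_missing_snps) > 0) {
    if (is.null(case_status))
      stop("case_status is required for differential missingness",
           call. = FALSE)
    j <- match(differential_missing_snps, snp_ids)
    if (anyNA(j)) stop("unknown SNP id in differential_missing_snps",
                       call. = FALSE)
    rate <- ifelse(case_status == 1L, diff_rate_case, diff_rate_control)
    for (jj in j) {
      miss <- stats::runif(n) < rate
      dos[miss, jj] <- NA_integer_
    }
  }

  out <- genotype_data(dos, geno$snp_map, geno$sample_table)
  attr(out, "true_freq") <- attr(geno, "true_freq")
  attr(out, "subpop") <- subpop
  attr(out, "related") <- related
  out
}

#' Simulate an ascertained case-control study efficiently
#'
#' Phenotypes depend only on the causal SNPs, so the simulator first draws
#' causal genotypes and liabilities for a large source population, ascertains
#' the requested numbers of cases and controls, and only then fills in the
#' non-causal SNPs for the ascertained individuals. This is distributionally
#' identical to simulating the full population genotype matrix and
#' subsetting, at a fraction of the cost.
#'
#' @param params A [sim_params()] object (trait 1 is used).
#' @param n_cases,n_controls Ascertained cohort sizes.
#' @param n_population Source population size; defaults to enough
#'   individuals to expect ~1.5x the requested cases.
#' @return List with `geno` (ascertained [genotype_data()]), `pheno` (0/1),
#'   `truth` (the [simulate_liability_pair()] output restricted to the
#'   ascertained individuals) and `case_proportion`.
#' @export
simulate_case_control_study <- function(params, n_cases, n_controls,
                                        n_population = NULL) {
  stopifnot(inherits(params, "sim_params"))
  if (is.null(n_population))
    n_population <- as.integer(ceiling(1.5 * n_cases / params$prevalence1))
  set.seed(params$seed)
  m <- params$n_snps
  nc <- params$n_causal
  freq <- stats::runif(m, params$maf_range[1], params$maf_range[2])
  causal <- sort(sample.int(m, nc))

  Xc <- matrix(stats::rbinom(n_population * nc, 2L,
                             rep(freq[causal], each = n_population)),
               nrow = n_population)
  f <- pmin(pmax(colMeans(Xc) / 2, 1e-6), 1 - 1e-6)
  Z <- sweep(sweep(Xc, 2, 2 * f), 2, sqrt(2 * f * (1 - f)), "/")

  blk <- if (!is.null(params$mhc_block))
    seq(params$mhc_block$start, params$mhc_block$end) else integer(0)
  share <- if (!is.null(params$mhc_block)) params$mhc_block$var_share else 0
  in_blk <- causal %in% blk
  w <- numeric(nc)
  if (share > 0 && any(in_blk)) {
    w[in_blk] <- share / sum(in_blk)
    w[!in_blk] <- (1 - share) / max(1L, sum(!in_blk))
  } else {
    w[] <- 1 / nc
  }
  beta <- sqrt(params$h2_trait1 * w) * stats::rnorm(nc)
  g <- drop(Z %*% beta)
  liab <- g + stats::rnorm(n_population, 0,
                           sqrt(max(0, 1 - params$h2_trait1)))
  thr <- stats::qnorm(1 - params$prevalence1)
  pheno_pop <- as.integer(liab > thr)

  asc <- ascertain_case_control(pheno_pop, n_cases, n_controls,
                                seed = params$seed + 7L)
  idx <- asc$idx
  n_sel <- length(idx)

  dos <- matrix(NA_integer_, n_sel, m)
  dos[, causal] <- Xc[idx, , drop = FALSE]
  noise <- setdiff(seq_len(m), causal)
  dos[, noise] <- matrix(stats::rbinom(n_sel * length(noise), 2L,
                                       rep(freq[noise], each = n_sel)),
                         nrow = n_sel)

  snp_map <- .layout_snp_map(m, 0L, params$mhc_block)
  st <- data.frame(id = sprintf("ind%05d", seq_len(n_sel)),
                   sex = NA_integer_,
                   phenotype = pheno_pop[idx] + 1L,
                   stringsAsFactors = FALSE)
  geno <- genotype_data(dos, snp_map, st)
  attr(geno, "true_freq") <- freq
  list(geno = geno,
       pheno = pheno_pop[idx],
       truth = list(effects = data.frame(index = causal, beta1 = beta),
                    genetic1 = g[idx], liability1 = liab[idx]),
       case_proportion = asc$case_proportion)
}

#' Simulate two ascertained disease cohorts sharing a control pool
#'
#' Draws a source population with two correlated liability-threshold traits
#' (genetic correlation `params$rg_true`), ascertains disjoint case cohorts
#' for each disease (comorbid individuals go to disease 1's cohort only if
#' not needed by the smaller design; here they are simply excluded from the
#' second cohort) and a shared pool of unaffected controls, then fills in
#' non-causal genotypes for the ascertained individuals only.
#'
#' @param params A [sim_params()] object.
#' @param n_cases1,n_cases2 Case-cohort sizes.
#' @param n_controls_pool Size of the shared (unaffected-by-both) control
#'   pool.
#' @param n_population Source population size; default sizes it from the
#'   rarer prevalence.
#' @return List with `geno`, `status` (0 = control, 1 = disease-1 case,
#'   2 = disease-2 case), `truth` (betas and ascertained genetic values).
#' @export
simulate_case_control_pair <- function(params, n_cases1, n_cases2,
                                       n_controls_pool,
                                       n_population = NULL) {
  stopifnot(inherits(params, "sim_params"))
  if (is.null(n_population))
    n_population <- as.integer(ceiling(
      2.0 * max(n_cases1, n_cases2) /
        min(params$prevalence1, params$prevalence2)))
  set.seed(params$seed)
  m <- params$n_snps
  nc <- params$n_causal
  freq <- stats::runif(m, params$maf_range[1], params$maf_range[2])
  causal <- sort(sample.int(m, nc))

  Xc <- matrix(stats::rbinom(n_population * nc, 2L,
                             rep(freq[causal], each = n_population)),
               nrow = n_population)
  f <- pmin(pmax(colMeans(Xc) / 2, 1e-6), 1 - 1e-6)
  Z <- sweep(sweep(Xc, 2, 2 * f), 2, sqrt(2 * f * (1 - f)), "/")

  blk <- if (!is.null(params$mhc_block))
    seq(params$mhc_block$start, params$mhc_block$end) else integer(0)
  share <- if (!is.null(params$mhc_block)) params$mhc_block$var_share else 0
  in_blk <- causal %in% blk
  w <- numeric(nc)
  if (share > 0 && any(in_blk)) {
    w[in_blk] <- share / sum(in_blk)
    w[!in_blk] <- (1 - share) / max(1L, sum(!in_blk))
  } else w[] <- 1 / nc

  rg <- params$rg_true
  u1 <- stats::rnorm(nc)
  u2 <- rg * u1 + sqrt(max(0, 1 - rg^2)) * stats::rnorm(nc)
  beta1 <- sqrt(params$h2_trait1 * w) * u1
  beta2 <- sqrt(params$h2_trait2 * w) * u2
  g1 <- drop(Z %*% beta1); g2 <- drop(Z %*% beta2)
  l1 <- g1 + stats::rnorm(n_population, 0, sqrt(max(0, 1 - params$h2_trait1)))
  l2 <- g2 + stats::rnorm(n_population, 0, sqrt(max(0, 1 - params$h2_trait2)))
  y1 <- l1 > stats::qnorm(1 - params$prevalence1)
  y2 <- l2 > stats::qnorm(1 - params$prevalence2)

  cases1_av <- which(y1)
  cases2_av <- setdiff(which(y2), cases1_av)  # comorbids stay with disease 1
  ctrl_av <- which(!y1 & !y2)
  if (length(cases1_av) < n_cases1)
    stop(sprintf("insufficient disease-1 cases: %d < %d",
                 length(cases1_av), n_cases1), call. = FALSE)
  if (length(cases2_av) < n_cases2)
    stop(sprintf("insufficient disease-2 cases: %d < %d",
                 length(cases2_av), n_cases2), call. = FALSE)
  if (length(ctrl_av) < n_controls_pool)
    stop("insufficient shared controls", call. = FALSE)
  set.seed(params$seed + 7L)
  sel1 <- sample(cases1_av, n_cases1)
  sel2 <- sample(cases2_av, n_cases2)
  sel0 <- sample(ctrl_av, n_controls_pool)
  idx <- c(sel1, sel2, sel0)
  status <- c(rep(1L, n_cases1), rep(2L, n_cases2),
              rep(0L, n_controls_pool))
  o <- order(idx)
  idx <- idx[o]; status <- status[o]
  n_sel <- length(idx)

  dos <- matrix(NA_integer_, n_sel, m)
  dos[, causal] <- Xc[idx, , drop = FALSE]
  noise <- setdiff(seq_len(m), causal)
  dos[, noise] <- matrix(stats::rbinom(n_sel * length(noise), 2L,
                                       rep(freq[noise], each = n_sel)),
                         nrow = n_sel)
  snp_map <- .layout_snp_map(m, 0L, params$mhc_block)
  st <- data.frame(id = sprintf("ind%05d", seq_len(n_sel)),
                   sex = NA_integer_,
                   phenotype = ifelse(status > 0L, 2L, 1L),
                   stringsAsFactors = FALSE)
  geno <- genotype_data(dos, snp_map, st)
  attr(geno, "true_freq") <- freq
  list(geno = geno, status = status,
       truth = list(effects = data.frame(index = causal,
                                         beta1 = beta1, beta2 = beta2),
                    genetic1 = g1[idx], genetic2 = g2[idx]))
}
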