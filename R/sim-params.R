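#' Simulation parameters for the liability-threshold genotype simulator
#'
#' Bundles every knob of the generative model: cohort and marker dimensions,
#' the allele-frequency spectrum, the causal architecture (number of causal
#' SNPs, per-trait liability-scale heritabilities, genetic correlation), the
#' population prevalence of each binary trait, and an optional "extended MHC"
#' block that concentrates a configurable share of the genetic variance in a
#' contiguous SNP window (mimicking the dense immune-gene region on
#' chromosome 6).
#'
#' @param n_individuals Number of individuals.
#' @param n_snps Number of autosomal SNPs (the MHC block, if any, is carved
#'   out of these).
#' @param maf_range Length-2 numeric in (0, 0.5]; allele frequencies are drawn
#'   uniformly from this interval.
#' @param n_causal Number of causal SNPs (must not exceed `n_snps`).
#' @param h2_trait1,h2_trait2 Liability-scale heritabilities in \[0, 1\].
#' @param rg_true Genetic correlation between the two traits' causal effects,
#'   in \[-1, 1\].
#' @param prevalence1,prevalence2 Population prevalences K in (0, 1); the
#'   liability threshold for trait t is `qnorm(1 - K_t)`.
#' @param mhc_block `NULL`, or a list with `start`, `end` (1-based SNP index
#'   range placed on chr6:26.5-34 Mb) and `var_share` (fraction of genetic
#'   variance assigned to causal SNPs inside the block).
#' @param n_snps_x Number of X-chromosome SNPs appended after the autosomes
#'   (males are simulated hemizygous with dosages coded 0/2).
#' @param male_fraction Fraction of males, used only when `n_snps_x > 0` or
#'   a sex column is wanted.
#' @param ld `NULL`, or a list with `block_size` (adjacent SNPs per LD block)
#'   and `flip_prob` (per-genotype resampling probability when copying within
#'   a block; smaller values give higher within-block r^2).
#' @param seed Integer seed making the whole simulation reproducible.
#'
#' @return An object of class `sim_params` (a validated list).
#' @export
sim_params <- function(n_individuals,
                       n_snps,
                       maf_range = c(0.05, 0.5),
                       n_causal = min(100L, n_snps),
                       h2_trait1 = 0.5,
                       h2_trait2 = 0.5,
                       rg_true = 0,
                       prevalence1 = 0.01,
                       prevalence2 = 0.01,
                       mhc_block = NULL,
                       n_snps_x = 0L,
                       male_fraction = 0.5,
                       ld = NULL,
                       seed = 1L) {
  stopifnot(length(n_individuals) == 1L, length(n_snps) == 1L)
  if (n_individuals < 1 || n_snps < 1)
    stop("n_individuals and n_snps must be positive", call. = FALSE)
  if (length(maf_range) != 2L || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2])
    stop("maf_range must lie within (0, 0.5] with min <= max", call. = FALSE)
  if (n_causal > n_snps)
    stop("n_causal must not exceed n_snps", call. = FALSE)
  if (abs(rg_true) > 1)
    stop("|rg_true| must be <= 1", call. = FALSE)
  for (h in c(h2_trait1, h2_trait2))
    if (h < 0 || h > 1) stop("heritabilities must lie in [0, 1]", call. = FALSE)
  for (K in c(prevalence1, prevalence2))
    if (K <= 0 || K >= 1) stop("prevalences must lie in (0, 1)", call. = FALSE)
  if (!is.null(mhc_block)) {
    stopifnot(is.list(mhc_block), all(c("start", "end") %in% names(mhc_block)))
    if (mhc_block$start < 1 || mhc_block$end > n_snps ||
        mhc_block$start > mhc_block$end)
      stop("mhc_block must be a valid SNP index range within 1..n_snps",
           call. = FALSE)
    if (is.null(mhc_block$var_share)) mhc_block$var_share <- 0
    if (mhc_block$var_share < 0 || mhc_block$var_share > 1)
      stop("mhc_block$var_share must lie in [0, 1]", call. = FALSE)
  }
  structure(list(
    n_individuals = as.integer(n_individuals),
    n_snps = as.integer(n_snps),
    maf_range = as.numeric(maf_range),
    n_causal = as.integer(n_causal),
    h2_trait1 = h2_trait1, h2_trait2 = h2_trait2,
    rg_true = rg_true,
    prevalence1 = prevalence1, prevalence2 = prevalence2,
    mhc_block = mhc_block,
    n_snps_x = as.integer(n_snps_x),
    male_fraction = male_fraction,
    ld = ld,
    seed = as.integer(seed)
  ), class = "sim_params")
}

#' Construct a genotype-data container
#'
#' The common carrier used by every stage of the pipeline: an individuals x
#' SNPs dosage matrix (counts of allele A1, `NA` = missing) plus a SNP map and
#' a sample table.
#'
#' @param dosage Integer matrix, individuals in rows, SNPs in columns; values
#'   0/1/2/`NA`. Row names are sample ids, column names SNP ids.
#' @param snp_map Data frame with columns `id`, `chr` (integer, 23 = X), `bp`
#'   (1-based), `a1`, `a2`, `region` (one of "autosome", "MHC", "X"), one row
#'   per dosage column.
#' @param sample_table Data frame with columns `id`, `sex` (1 = male,
#'   2 = female, `NA` unknown), `phenotype`.
#' @return An object of class `genotype_data`.
#' @export
genotype_data <- function(dosage, snp_map, sample_table) {
  stopifnot(is.matrix(dosage))
  if (nrow(snp_map) != ncol(dosage))
    stop("snp_map must have one row per SNP column", call. = FALSE)
  if (nrow(sample_table) != nrow(dosage))
    stop("sample_table must have one row per individual", call. = FALSE)
  bad <- !(dosage %in% c(0L, 1L, 2L) | is.na(dosage))
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA", call. = FALSE)
  rownames(dosage) <- sample_table$id
  colnames(dosage) <- snp_map$id
  structure(list(dosage = dosage, snp_map = snp_map,
                 sample_table = sample_table),
            class = "genotype_data")
}

#' @export
print.genotype_data <- function(x, ...) {
  cat(sprintf("genotype_data: %d individuals x %d SNPs (%d autosomal, %d MHC, %d X); %.2f%% missing\n",
              nrow(x$dosage), ncol(x$dosage),
              sum(x$snp_map$region == "autosome"),
              sum(x$snp_map$region == "MHC"),
              sum(x$snp_map$region == "X"),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' @export
dim.genotype_data <- function(x) dim(x$dosage)

# Subset a genotype_data by individuals (i) and/or SNPs (j).
#' Subset a genotype-data object
#' @param geno A `genotype_data` object.
#' @param i Row (individual) index vector, or `NULL` to keep all.
#' @param j Column (SNP) index vector (integer, logical, or SNP ids), or
#'   `NULL` to keep all.
#' @return A `genotype_data` with the selected individuals and SNPs.
#' @export
subset_geno <- function(geno, i = NULL, j = NULL) {
  if (is.null(i)) i <- seq_len(nrow(geno$dosage))
  if (is.null(j)) j <- seq_len(ncol(geno$dosage))
  if (is.character(j)) j <- match(j, geno$snp_map$id)
  if (is.character(i)) i <- match(i, geno$sample_table$id)
  genotype_data(geno$dosage[i, j, drop = FALSE],
                geno$snp_map[j, , drop = FALSE],
                geno$sample_table[i, , drop = FALSE])
}
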