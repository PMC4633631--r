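#' Pipeline run configuration
#'
#' Gathers everything the end-to-end drivers need: a genotype source (a
#' PLINK prefix or a [sim_params()] object), the per-disease population
#' prevalence table, QC thresholds, PC counts (10 for association, 20 for
#' REML, following common practice for this design), and seeds. A single
#' root seed deterministically derives per-stage seeds so stages are
#' reproducible yet independent.
#'
#' @param source PLINK fileset prefix (character) or a `sim_params` object.
#' @param prevalence Named numeric vector, population prevalence per
#'   disease.
#' @param qc A [qc_thresholds()] object.
#' @param prune A [prune_spec()] object.
#' @param n_pcs_assoc,n_pcs_reml PC counts used as covariates.
#' @param relatedness_threshold GRM cutoff for [prune_related()].
#' @param outlier_sd,outlier_top_k Ancestry-outlier rule.
#' @param seed Root seed.
#' @param out_dir Output directory (created if needed); `NULL` disables
#'   file output.
#' @return A list of class `run_config`.
#' @export
run_config <- function(source, prevalence,
                       qc = qc_thresholds(), prune = prune_spec(),
                       n_pcs_assoc = 10L, n_pcs_reml = 20L,
                       relatedness_threshold = 0.05,
                       outlier_sd = 6.0, outlier_top_k = 10L,
                       seed = 1L, out_dir = NULL) {
  if (is.null(names(prevalence)) || any(!nzchar(names(prevalence))))
    stop("prevalence must be a named vector", call. = FALSE)
  if (any(prevalence <= 0 | prevalence >= 1))
    stop("prevalences must lie in (0, 1)", call. = FALSE)
  structure(list(source = source, prevalence = prevalence, qc = qc,
                 prune = prune, n_pcs_assoc = as.integer(n_pcs_assoc),
                 n_pcs_reml = as.integer(n_pcs_reml),
                 relatedness_threshold = relatedness_threshold,
                 outlier_sd = outlier_sd,
                 outlier_top_k = as.integer(outlier_top_k),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

.stage_seed <- function(config, stage) {
  # deterministic per-stage seed derived from the root seed; arithmetic in
  # doubles to avoid 32-bit overflow, result kept < 2^31
  as.integer((as.numeric(config$seed) * 10007 +
                sum(utf8ToInt(stage))) %% 2000000011)
}

.load_source <- function(config) {
  if (inherits(config$source, "sim_params")) {
    simulate_genotypes(config$source)
  } else {
    read_plink(config$source)
  }
}

#' Run the univariate heritability pipeline for one disease
#'
#' QC (sample then SNP filters) -> LD pruning + PCA + ancestry-outlier
#' removal -> GRM construction (all autosomes, autosomes minus the extended
#' MHC, optionally X) -> relatedness pruning -> REML per region with the
#' top-PC covariates -> liability-scale transform at the configured
#' prevalence -> MHC percentage. Returns the per-stage objects plus a
#' one-row summary; writes TSVs and a log under `out_dir` when configured.
#'
#' @param config A [run_config()] object.
#' @param disease Name of the disease (must index `config$prevalence`).
#' @param geno Optional pre-loaded [genotype_data()] (otherwise loaded from
#'   `config$source`).
#' @param case_status Optional 0/1 vector; defaults to the genotype file's
#'   phenotype column (2 = case).
#' @return List with `summary` (data frame), `fits`, `qc_reports`,
#'   `kept_samples`, `pca`.
#' @export
run_univariate <- function(config, disease, geno = NULL,
                           case_status = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (!disease %in% names(config$prevalence))
    stop("no prevalence entry for disease '", disease, "'", call. = FALSE)
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }

  if (is.null(geno)) geno <- .load_source(config)
  if (is.null(case_status)) {
    case_status <- as.integer(geno$sample_table$phenotype == 2L)
    if (anyNA(case_status)) stop("phenotype column incomplete", call. = FALSE)
  }

  fs <- filter_samples(geno, config$qc)
  keep_i <- match(fs$report$retained_ids, geno$sample_table$id)
  case_status <- case_status[keep_i]
  geno <- fs$geno
  say("samples: %d retained (%d removed by call rate)",
      fs$report$n_retained, fs$report$removed[["call_rate"]])

  fq <- filter_snps(geno, case_status, config$qc)
  geno <- fq$geno
  say("SNPs: %d retained (removed: %s)", fq$report$n_retained,
      paste(names(fq$report$removed), fq$report$removed,
            sep = "=", collapse = ", "))

  pruned <- ld_prune(geno, config$prune, max_snps = 100000L)
  say("LD pruning: %d SNPs in the pruned set", length(pruned))
  k_need <- max(config$n_pcs_reml, config$n_pcs_assoc)
  pca <- compute_pca(geno, pruned, k = k_need)
  outliers <- remove_pca_outliers(pca, config$outlier_sd,
                                  config$outlier_top_k)
  say("ancestry outliers flagged: %d", length(outliers))
  if (length(outliers) > 0) {
    keep <- !(geno$sample_table$id %in% outliers)
    geno <- subset_geno(geno, i = which(keep))
    case_status <- case_status[keep]
    pca <- compute_pca(geno, intersect(pruned, geno$snp_map$id),
                       k = k_need)
  }

  parts <- partition_snps(geno$snp_map)
  grm_auto <- build_grm(geno, parts$auto, region = "auto")
  kept <- prune_related(grm_auto, config$relatedness_threshold,
                        call_rate = rowMeans(!is.na(geno$dosage)))
  say("relatedness pruning: %d of %d samples retained", length(kept),
      nrow(geno$dosage))
  sel <- match(kept, geno$sample_table$id)
  geno <- subset_geno(geno, i = sel)
  case_status <- case_status[sel]
  pcs <- pca$scores[sel, seq_len(config$n_pcs_reml), drop = FALSE]

  parts <- partition_snps(geno$snp_map)
  grm_auto <- build_grm(geno, parts$auto, region = "auto")
  grm_ex <- build_grm(geno, parts$auto_exMHC, region = "auto_exMHC")

  fit_auto <- reml_fit(case_status, grm_auto, covariates = pcs)
  fit_ex <- reml_fit(case_status, grm_ex, covariates = pcs)
  say("h2_obs auto = %.4f (se %.4f); exMHC = %.4f", fit_auto$h2_obs,
      fit_auto$h2_se, fit_ex$h2_obs)

  K <- config$prevalence[[disease]]
  P <- mean(case_status)
  li_auto <- observed_to_liability(fit_auto$h2_obs, K, P, fit_auto$h2_se)
  li_ex <- observed_to_liability(fit_ex$h2_obs, K, P, fit_ex$h2_se)

  fit_x <- NULL
  li_x <- list(h2_liab = NA_real_, se_liab = NA_real_)
  if (length(parts$X) > 0 && !anyNA(geno$sample_table$sex)) {
    grm_x <- build_grm_x(geno)
    fit_x <- reml_fit(case_status, grm_x, covariates = pcs)
    li_x <- observed_to_liability(fit_x$h2_obs, K, P, fit_x$h2_se)
  }

  summary <- data.frame(
    disease = disease, n_cases = sum(case_status == 1L),
    n_controls = sum(case_status == 0L), K = K, P = P,
    h2_liab_auto = li_auto$h2_liab, se_auto = li_auto$se_liab,
    p_auto = fit_auto$lrt_p,
    h2_liab_exmhc = li_ex$h2_liab, se_exmhc = li_ex$se_liab,
    p_exmhc = fit_ex$lrt_p,
    pct_mhc = pct_mhc(li_auto$h2_liab, li_ex$h2_liab),
    h2_liab_x = li_x$h2_liab, se_x = li_x$se_liab,
    p_x = if (is.null(fit_x)) NA_real_ else fit_x$lrt_p,
    stringsAsFactors = FALSE)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(summary,
                       file.path(config$out_dir,
                                 paste0(disease, "_h2.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(log_lines, file.path(config$out_dir,
                                    paste0(disease, "_log.txt")))
  }
  list(summary = summary,
       fits = list(auto = fit_auto, exMHC = fit_ex, X = fit_x),
       qc_reports = list(sample = fs$report, snp = fq$report),
       kept_samples = kept, pca = pca)
}

#' Run the pairwise co-heritability stage for two disease cohorts
#'
#' Splits the shared control pool evenly (seeded), recomputes PCs on the
#' combined pair cohort, builds GRMs with and without the extended MHC, and
#' fits the bivariate model for each. Returns a one-row report carrying
#' both rG estimates, the nominal exMHC p and Bonferroni-adjusted columns.
#'
#' @param config A [run_config()] object.
#' @param geno A post-QC [genotype_data()] for the combined samples.
#' @param status Vector with 0 = shared control, 1 = disease-1 case,
#'   2 = disease-2 case.
#' @param pair_name Label, e.g. "UC-CD".
#' @param n_tests_relaxed,n_tests_strict Bonferroni denominators (9 and 45
#'   by convention for 10 cohorts).
#' @return List with `summary` (one-row data frame) and the two
#'   `bivar_fit`s.
#' @export
run_pairwise <- function(config, geno, status, pair_name = "D1-D2",
                         n_tests_relaxed = 9L, n_tests_strict = 45L) {
  stopifnot(inherits(config, "run_config"))
  ids <- geno$sample_table$id
  ctrl <- ids[status == 0L]
  alloc <- split_controls(ctrl, seed = .stage_seed(config, "split"))
  s1 <- c(ids[status == 1L], alloc$controls1)
  s2 <- c(ids[status == 2L], alloc$controls2)
  i1 <- match(s1, ids); i2 <- match(s2, ids)
  y1 <- as.integer(status[i1] == 1L)
  y2 <- as.integer(status[i2] == 2L)

  ord <- c(i1, i2)
  geno_o <- subset_geno(geno, i = ord)
  pruned <- ld_prune(geno_o, config$prune, max_snps = 100000L)
  pca <- compute_pca(geno_o, pruned, k = config$n_pcs_reml)
  pcs <- pca$scores

  parts <- partition_snps(geno_o$snp_map)
  grm_auto <- build_grm(geno_o, parts$auto, region = "auto")
  grm_ex <- build_grm(geno_o, parts$auto_exMHC, region = "auto_exMHC")

  fit_auto <- bivar_reml(y1, y2, grm_auto, covariates = pcs)
  fit_ex <- bivar_reml(y1, y2, grm_ex, covariates = pcs)

  summary <- data.frame(
    pair = pair_name,
    rg_auto = fit_auto$rG, se_auto = fit_auto$rG_se,
    p_auto = fit_auto$lrt_p,
    rg_exmhc = fit_ex$rG, se_exmhc = fit_ex$rG_se,
    p_nominal = fit_ex$lrt_p,
    p_adj = bonferroni_adjust(fit_ex$lrt_p, n_tests_relaxed),
    p_adj_strict = bonferroni_adjust(fit_ex$lrt_p, n_tests_strict),
    stringsAsFactors = FALSE)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(summary,
                       file.path(config$out_dir,
                                 paste0(gsub("[^A-Za-z0-9]", "_",
                                             pair_name), "_rg.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(summary = summary, fits = list(auto = fit_auto, exMHC = fit_ex))
}
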