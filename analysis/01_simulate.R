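#!/usr/bin/env Rscript
# Simulate the synthetic biobank: genotypes with an extended-MHC block,
# two correlated liability-threshold diseases ascertained against a shared
# control pool, QC artifacts (missingness, HWE failures, a related pair),
# and write the cohort as a PLINK fileset plus a truth sidecar.

source("analysis/00_config.R")
set.seed(root_seed)

p <- sim_params(1, scenario$n_snps, maf_range = c(0.05, 0.5),
                n_causal = 300, h2_trait1 = scenario$h2_1,
                h2_trait2 = scenario$h2_2, rg_true = scenario$rg,
                prevalence1 = scenario$K1, prevalence2 = scenario$K2,
                mhc_block = scenario$mhc_block, seed = root_seed)
sim <- simulate_case_control_pair(p, scenario$n_cases1, scenario$n_cases2,
                                  scenario$n_controls)
geno <- sim$geno
status <- sim$status
message(sprintf("ascertained cohort: %d D1 cases, %d D2 cases, %d controls",
                sum(status == 1), sum(status == 2), sum(status == 0)))

# an unrelated comparator phenotype: pure noise at the same prevalence scale
set.seed(root_seed + 1L)
nul_pheno <- rbinom(nrow(geno$dosage), 1, 0.2)

# inject QC artifacts so the next stage has real work to do
snp_ids <- geno$snp_map$id
geno <- inject_artifacts(
  geno,
  missing_rate_per_snp = stats::setNames(c(0.10, 0.08), snp_ids[1:2]),
  differential_missing_snps = snp_ids[3],
  hwe_violation_snps = snp_ids[4:5],
  n_related_pairs = 2L,
  case_status = as.integer(status > 0),
  seed = root_seed + 2L)
# sprinkle light random missingness everywhere
geno <- inject_artifacts(geno, missing_rate_per_snp = 0.002,
                         seed = root_seed + 3L)

geno$sample_table$phenotype <- ifelse(status > 0L, 2L, 1L)
write_plink(geno, file.path(sim_dir, "cohort"))
write.table(
  data.frame(id = geno$sample_table$id, status = status, nul = nul_pheno),
  file.path(sim_dir, "status.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE)
write.table(sim$truth$effects, file.path(sim_dir, "true_effects.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("wrote PLINK fileset + truth sidecar under ", sim_dir)
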