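#!/usr/bin/env Rscript
# Quality control and population structure: sample/SNP filters, LD pruning,
# principal components, ancestry outliers. Writes the QC report, the prune
# list and the PC scores.

source("analysis/00_config.R")

geno <- read_plink(file.path(sim_dir, "cohort"))
status <- read.table(file.path(sim_dir, "status.tsv"), header = TRUE)
stopifnot(identical(geno$sample_table$id, as.character(status$id)))
case_any <- as.integer(status$status > 0)

fs <- filter_samples(geno)
print(fs$report)
keep <- match(fs$report$retained_ids, geno$sample_table$id)
geno <- fs$geno
case_any <- case_any[keep]

fq <- filter_snps(geno, case_any)
print(fq$report)
geno <- fq$geno

pruned <- ld_prune(geno, prune_spec(), max_snps = 100000L)
message(length(pruned), " SNPs in the pruned set")
pca <- compute_pca(geno, pruned, k = 20)
outliers <- remove_pca_outliers(pca)
message(length(outliers), " ancestry outliers flagged")

qc_tab <- data.frame(
  stage = c("samples_in", "samples_kept", "snps_in", "snps_kept",
            names(fq$report$removed)),
  count = c(fs$report$n_input, fs$report$n_retained, fq$report$n_input,
            fq$report$n_retained, unname(fq$report$removed)))
write.table(qc_tab, file.path(out_dir, "qc_report.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
writeLines(pruned, file.path(out_dir, "prune.in"))
write.table(cbind(FID = rownames(pca$scores), IID = rownames(pca$scores),
                  round(pca$scores, 6)),
            file.path(out_dir, "pcs.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
message("wrote qc_report.tsv, prune.in, pcs.tsv under ", out_dir)
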