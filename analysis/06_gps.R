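#!/usr/bin/env Rscript
# Genome-wide pairwise sharing: the threshold-free max-min statistic on the
# GWAS Z-scores of every trait pair, MHC excluded, with analytic
# hypergeometric p-values Bonferroni-adjusted over pairs.

source("analysis/00_config.R")

traits <- c("D1", "D2", "NUL")
assoc <- lapply(traits, function(tr) {
  tab <- read.table(file.path(out_dir, paste0("assoc_", tr, ".tsv")),
                    header = TRUE)
  data.frame(snp = tab$SNP, p = tab$P, chr = tab$CHR, bp = tab$BP)
})
names(assoc) <- traits

res <- gps_all_pairs(assoc, exclude_mhc = TRUE)
write.table(res$pairs, file.path(out_dir, "gps_pairs.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(res$p_matrix, file.path(out_dir, "gps_p_matrix.tsv"),
            sep = "\t", quote = FALSE, col.names = NA)
message("pairwise sharing test (MHC excluded):")
print(res$pairs[, c("pair", "gamma", "a", "b", "n", "p_analytic",
                    "p_adj")], row.names = FALSE)
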