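#!/usr/bin/env Rscript
# RNA-seq preprocessing, one cancer type at a time.
#
# For each cancer type: low-expression filter (CPM >= 1 in >= 20% of
# samples), GC-stratified within-sample adjustment plus between-sample
# quantile normalization, log2(CPM + 0.25), PCA outlier removal (2 PCs,
# 3x RMS distance), duplicate/small-batch removal (batches <= 4 dropped),
# ComBat batch correction, and exclusion of subtypes with < 10 tumors.
# Writes one log-expression matrix per type plus the retained metadata.

library(mhcprofiler)

cohort <- read_cohort("results/cohort")
dir.create("results/preprocessed", showWarnings = FALSE, recursive = TRUE)

md_all <- cohort$metadata
kept <- list()
for (ct in unique(md_all$cancer_type)) {
  sel <- md_all$sample_id[md_all$cancer_type == ct]
  pp <- preprocess_expression(cohort$counts[, sel, drop = FALSE], cohort$gc,
                              md_all[md_all$sample_id %in% sel, , drop = FALSE])
  write_matrix_tsv(pp$expr, sprintf("results/preprocessed/expr_%s.tsv", ct),
                   "gene_id")
  kept[[ct]] <- pp$metadata
  cat(sprintf("%s: %d genes x %d samples retained (of %d)\n",
              ct, nrow(pp$expr), ncol(pp$expr), length(sel)))
}
md <- do.call(rbind, kept)
rownames(md) <- NULL
utils::write.table(md, "results/preprocessed/metadata.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat(sprintf("total: %d of %d samples retained across %d types\n",
            nrow(md), nrow(md_all), length(kept)))
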