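#!/usr/bin/env Rscript
# MHC-gene mutation frequencies and the pan-cancer correlation summary.
#
# Reports, per molecular subtype, the percentage of tumors carrying at
# least one nonsilent mutation in the MHC gene set, and builds the signed
# pan-cancer summary of strong inter-immunomodulator correlations
# (+1 / -1 per cancer type, summed over types).

library(mhcprofiler)

cohort <- read_cohort("results/cohort")
md <- read.delim("results/preprocessed/metadata.tsv")
panel <- read.delim("results/panel_retained.tsv")
types <- unique(md$cancer_type)

mut_genes <- cohort$panel$gene_id[cohort$panel$class == "MHC"]
freq <- mhc_mutation_frequency(cohort$mutations, mut_genes, md)
utils::write.table(freq, "results/mutation_freq.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat(sprintf("MHC mutation frequency across %d subtypes: %d%% - %d%%\n",
            nrow(freq), min(freq$frequency), max(freq$frequency)))
for (ct in types[1:2]) {
  f <- freq[freq$cancer_type == ct, ]
  cat(sprintf("  %s: %s\n", ct,
              paste(f$subtype, f$frequency, sep = " = ", collapse = "; ")))
}

tumors <- md$sample_id[md$is_tumor == 1L]
vars_by_type <- lapply(types, function(ct) {
  e <- read_matrix_tsv(sprintf("results/preprocessed/expr_%s.tsv", ct))
  e <- e[intersect(panel$gene_id, rownames(e)), , drop = FALSE]
  tum <- intersect(colnames(e), tumors)
  tc <- cohort$truth$tcell[tum, ]
  rbind(e[, tum, drop = FALSE], TCD4 = tc[, "TCD4"], TCD8 = tc[, "TCD8"])
})
names(vars_by_type) <- types
cs <- pan_cancer_correlation_summary(vars_by_type)
write_matrix_tsv(cs$summary, "results/corr_summary.tsv", "variable")
s <- cs$summary[upper.tri(cs$summary)]
cat(sprintf("correlation summary over %d types: %d pairs with |score| >= 5, range [%d, %d]\n",
            cs$n_types, sum(abs(s) >= 5, na.rm = TRUE),
            min(s, na.rm = TRUE), max(s, na.rm = TRUE)))
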