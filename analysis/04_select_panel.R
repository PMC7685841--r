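#!/usr/bin/env Rscript
# Panel selection: suppress immune-infiltrate confounding.
#
# Removes immunomodulator panel genes that are (a) lowly expressed in at
# least one subtype of any cancer type, or (b) strongly (rho >= 0.4) and
# significantly (BH q <= 0.05) Spearman-correlated with the estimated
# immune fraction in any cancer type (tumor samples only). The retained
# panel is the substrate for the relative-effect and clustering steps.

library(mhcprofiler)

cohort <- read_cohort("results/cohort")
md <- read.delim("results/preprocessed/metadata.tsv")
types <- unique(md$cancer_type)
expr_by_type <- lapply(types, function(ct)
  read_matrix_tsv(sprintf("results/preprocessed/expr_%s.tsv", ct)))
names(expr_by_type) <- types
fr <- read.delim("results/fractions.tsv")
immune <- setNames(fr$immune, fr$sample_id)

low_flagged <- flag_low_expressed_panel(expr_by_type, md, cohort$panel,
                                        min_median_logcpm = 0)
panel_expr <- cohort$panel[!cohort$panel$gene_id %in% low_flagged, ]
filt <- immune_correlation_filter(expr_by_type, immune, md, panel_expr,
                                  r_threshold = 0.4, fdr = 0.05,
                                  mode = "positive")

utils::write.table(filt$panel, "results/panel_retained.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(filt$report, "results/panel_filter_report.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

cat(sprintf("panel: %d genes in, %d flagged lowly expressed, %d immune-correlated\n",
            nrow(cohort$panel), length(low_flagged), length(filt$removed)))
cat(sprintf("retained: %d genes (%s)\n", nrow(filt$panel),
            paste(names(table(filt$panel$class)), table(filt$panel$class),
                  sep = "=", collapse = ", ")))
driven <- names(cohort$truth$immune_driven)[cohort$truth$immune_driven]
cat(sprintf("of %d planted immune-driven panel genes, %d survived the filter\n",
            sum(driven %in% cohort$panel$gene_id),
            sum(filt$panel$gene_id %in% driven)))
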