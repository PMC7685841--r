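#!/usr/bin/env Rscript
# Unsupervised clustering of MHC expression probabilities.
#
# Clusters the subtype-by-MHC-gene probability matrix with hierarchical
# clustering, k-means and PAM over K = 2..5, selects K by rank aggregation
# of the 12-index validity battery, forms the Hungarian-aligned majority
# consensus, labels clusters MHC-low / MHC-intermediate / MHC-high by
# ascending mean probability, and compares the result with the planted
# archetypes.

library(mhcprofiler)

cohort <- read_cohort("results/cohort")
panel <- read.delim("results/panel_retained.tsv")
eff <- read_matrix_tsv("results/effects.tsv")
mhc <- intersect(panel$gene_id[panel$class == "MHC"], colnames(eff))
m <- eff[, mhc]

clu <- cluster_mhc(m, K_range = 2:5, seed = derive_seed(1L, "cluster"))
cat(sprintf("mean validity ranks per K: %s\n",
            paste(names(clu$mean_ranks), round(clu$mean_ranks, 2),
                  sep = ":", collapse = "  ")))
cat(sprintf("selected K = %d\n", clu$result$selected_K))

clusters <- data.frame(subtype = names(clu$result$consensus),
                       consensus_cluster = unname(clu$result$consensus),
                       mhc_class = unname(clu$result$subtype_class),
                       mean_mhc_probability = rowMeans(m))
utils::write.table(clusters, "results/clusters.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(clu$validity, "results/validity.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
write_matrix_tsv(clu$heatmap_matrix, "results/heatmap_matrix.tsv", "subtype")

comp <- table(clusters$mhc_class)
cat(sprintf("cluster sizes: %s\n",
            paste(names(comp), comp, sep = "=", collapse = ", ")))
arch <- cohort$truth$archetype
key <- paste(arch$cancer_type, arch$subtype, sep = "::")
planted <- arch$archetype[match(clusters$subtype, key)]
agree <- table(planted = planted, assigned = clusters$mhc_class)
print(agree)
cat(sprintf("cluster means (low/int/high): %s\n",
            paste(round(clu$result$cluster_means, 3), collapse = " / ")))
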