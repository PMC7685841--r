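#' Nonsilent MAF variant classes
#'
#' The conventional nonsynonymous Variant_Classification vocabulary used when
#' counting mutation burden from MAF-like tables.
#'
#' @return character vector of class names.
#' @export
maf_nonsilent_classes <- function() {
  c("Missense_Mutation", "Nonsense_Mutation", "Frame_Shift_Del",
    "Frame_Shift_Ins", "In_Frame_Del", "In_Frame_Ins", "Splice_Site",
    "Translation_Start_Site", "Nonstop_Mutation")
}

## accept standard MAF column names as an aliased dialect
normalize_mutation_table <- function(mutations) {
  aliases <- c(Tumor_Sample_Barcode = "sample_id", Hugo_Symbol = "gene",
               Variant_Classification = "variant_class")
  for (a in names(aliases)) {
    if (a %in% names(mutations) && !aliases[[a]] %in% names(mutations)) {
      names(mutations)[names(mutations) == a] <- aliases[[a]]
    }
  }
  need <- c("sample_id", "gene", "variant_class")
  if (!all(need %in% names(mutations))) {
    stopf("mutation table must have columns %s (or MAF aliases)",
          paste(need, collapse = ", "))
  }
  mutations
}

#' Per-sample nonsilent mutation burden (gene level)
#'
#' Counts, for each sample, the number of distinct genes carrying at least
#' one nonsilent mutation: multiple records for the same gene in the same
#' sample count once. Silent records are dropped (with the dropped count
#' reported via a message). Samples absent from the table get burden 0.
#'
#' @param mutations data.frame with `sample_id`, `gene`, `variant_class`
#'   (MAF column names `Tumor_Sample_Barcode`/`Hugo_Symbol`/
#'   `Variant_Classification` are accepted).
#' @param sample_ids samples for which to report burden; defaults to those in
#'   the table.
#' @param nonsilent character vector of variant classes counted as nonsilent.
#' @param per_event if `TRUE`, count mutation events instead of mutated genes.
#' @return named integer vector of burdens over `sample_ids`.
#' @export
per_sample_mutation_burden <- function(mutations,
                                       sample_ids = NULL,
                                       nonsilent = maf_nonsilent_classes(),
                                       per_event = FALSE) {
  mutations <- normalize_mutation_table(mutations)
  keep <- mutations$variant_class %in% nonsilent
  n_silent <- sum(!keep)
  if (n_silent > 0) {
    message(sprintf("dropped %d silent mutation record(s)", n_silent))
  }
  mutations <- mutations[keep, , drop = FALSE]
  if (is.null(sample_ids)) sample_ids <- unique(mutations$sample_id)
  if (!per_event) {
    mutations <- unique(mutations[, c("sample_id", "gene")])
  }
  tab <- table(factor(mutations$sample_id, levels = sample_ids))
  stats::setNames(as.integer(tab), sample_ids)
}

#' Per-subtype MHC-gene mutation frequency
#'
#' For each molecular subtype, the percentage of tumor samples carrying at
#' least one nonsilent mutation in at least one gene of `gene_set`. The gene
#' set is a required input: the mutation analysis uses its own MHC gene list,
#' never one inferred from the expression panel.
#'
#' @param mutations MAF-like data.frame (see [per_sample_mutation_burden()]).
#' @param gene_set character vector of MHC genes for the mutation analysis.
#' @param metadata sample metadata with `sample_id`, `cancer_type`,
#'   `subtype`, `is_tumor`.
#' @param nonsilent nonsilent variant class vocabulary.
#' @return data.frame with `cancer_type`, `subtype`, `n_samples`,
#'   `n_carriers`, `frequency_exact` and `frequency` (rounded to integer
#'   percent, the reporting convention).
#' @export
mhc_mutation_frequency <- function(mutations, gene_set, metadata,
                                   nonsilent = maf_nonsilent_classes()) {
  if (length(gene_set) == 0L) stopf("gene_set must be non-empty")
  mutations <- normalize_mutation_table(mutations)
  mutations <- mutations[mutations$variant_class %in% nonsilent &
                           mutations$gene %in% gene_set, , drop = FALSE]
  carriers <- unique(mutations$sample_id)
  tumors <- metadata[metadata$is_tumor == 1L, , drop = FALSE]
  key <- unique(tumors[, c("cancer_type", "subtype")])
  out <- lapply(seq_len(nrow(key)), function(i) {
    sel <- tumors$cancer_type == key$cancer_type[i] &
      tumors$subtype == key$subtype[i]
    n <- sum(sel)
    if (n == 0L) {
      warnf("subtype %s::%s has no samples; omitted",
            key$cancer_type[i], key$subtype[i])
      return(NULL)
    }
    k <- sum(tumors$sample_id[sel] %in% carriers)
    data.frame(cancer_type = key$cancer_type[i], subtype = key$subtype[i],
               n_samples = n, n_carriers = k,
               frequency_exact = 100 * k / n,
               frequency = as.integer(round(100 * k / n)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
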