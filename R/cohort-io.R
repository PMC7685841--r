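#' Write a cohort to a directory of TSV files
#'
#' Emits `counts.tsv`, `gc.tsv`, `betas.tsv`, `reference.tsv`,
#' `tcell_reference.tsv`, `metadata.tsv`, `panel.tsv`, `mutations.tsv`,
#' `truth.tsv` and `archetypes.tsv`. All matrices use a header row and a
#' row-name first column; the set round-trips through [read_cohort()].
#'
#' @param cohort a `"cohort"` from [generate_cohort()].
#' @param directory output directory, created if absent.
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, directory) {
  if (!inherits(cohort, "cohort")) stopf("not a cohort object")
  if (ncol(cohort$counts) == 0L || nrow(cohort$metadata) == 0L) {
    stopf("refusing to write an empty cohort (0 samples)")
  }
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(directory, f)
  write_matrix_tsv(cohort$counts, p("counts.tsv"), "gene_id")
  write_df_tsv(data.frame(gene_id = names(cohort$gc), gc = cohort$gc),
               p("gc.tsv"))
  write_matrix_tsv(cohort$betas, p("betas.tsv"), "cpg_id")
  write_matrix_tsv(cohort$reference, p("reference.tsv"), "cpg_id")
  write_matrix_tsv(cohort$tcell_reference, p("tcell_reference.tsv"), "cpg_id")
  write_df_tsv(cohort$metadata, p("metadata.tsv"))
  write_df_tsv(cohort$panel, p("panel.tsv"))
  write_df_tsv(cohort$mutations, p("mutations.tsv"))
  truth_df <- data.frame(sample_id = rownames(cohort$truth$fractions),
                         cohort$truth$fractions, cohort$truth$tcell,
                         check.names = FALSE)
  write_df_tsv(truth_df, p("truth.tsv"))
  write_df_tsv(cohort$truth$archetype, p("archetypes.tsv"))
  if (!is.null(cohort$truth$immune_driven)) {
    write_df_tsv(data.frame(gene_id = names(cohort$truth$immune_driven),
                            immune_driven = as.integer(cohort$truth$immune_driven)),
                 p("gene_truth.tsv"))
  }
  invisible(directory)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param directory directory containing the TSV file set.
#' @return a list of class `"cohort"`. The `truth` element carries only what
#'   is serialized (cell fractions, T-cell levels, archetypes).
#' @export
read_cohort <- function(directory) {
  p <- function(f) file.path(directory, f)
  for (f in c("counts.tsv", "gc.tsv", "betas.tsv", "reference.tsv",
              "metadata.tsv", "panel.tsv", "mutations.tsv")) {
    if (!file.exists(p(f))) stopf("missing cohort file: %s", f)
  }
  gc_df <- read_df_tsv(p("gc.tsv"))
  truth <- NULL
  if (file.exists(p("truth.tsv"))) {
    td <- read_df_tsv(p("truth.tsv"))
    fr <- as.matrix(td[, c("epithelial", "fibroblast", "immune")])
    tc <- as.matrix(td[, c("TCD4", "TCD8")])
    rownames(fr) <- rownames(tc) <- td$sample_id
    truth <- list(fractions = fr, tcell = tc)
    if (file.exists(p("archetypes.tsv"))) {
      truth$archetype <- read_df_tsv(p("archetypes.tsv"))
    }
    if (file.exists(p("gene_truth.tsv"))) {
      gt <- read_df_tsv(p("gene_truth.tsv"))
      truth$immune_driven <- stats::setNames(gt$immune_driven == 1L, gt$gene_id)
    }
  }
  tref <- if (file.exists(p("tcell_reference.tsv"))) {
    read_matrix_tsv(p("tcell_reference.tsv"))
  }
  structure(list(
    counts = read_matrix_tsv(p("counts.tsv")),
    gc = stats::setNames(gc_df$gc, gc_df$gene_id),
    betas = read_matrix_tsv(p("betas.tsv")),
    reference = read_matrix_tsv(p("reference.tsv")),
    tcell_reference = tref,
    metadata = read_df_tsv(p("metadata.tsv")),
    panel = read_df_tsv(p("panel.tsv")),
    mutations = read_df_tsv(p("mutations.tsv")),
    truth = truth), class = "cohort")
}
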