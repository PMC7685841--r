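#' Filter lowly expressed genes
#'
#' Retains genes with counts-per-million at or above `min_cpm` in at least
#' `min_fraction` of samples (both boundaries inclusive). The sample set is
#' unchanged.
#'
#' @param counts gene-by-sample count matrix (non-negative).
#' @param min_cpm CPM threshold (> 0); default 1.
#' @param min_fraction required fraction of samples in (0, 1]; default 0.2.
#' @return the filtered count matrix.
#' @export
filter_low_expression <- function(counts, min_cpm = 1, min_fraction = 0.2) {
  if (min_cpm <= 0) stopf("min_cpm must be > 0")
  if (min_fraction <= 0 || min_fraction > 1) stopf("min_fraction must be in (0,1]")
  libsize <- colSums(counts)
  if (any(libsize == 0)) stopf("zero library size in sample(s): %s",
                               paste(colnames(counts)[libsize == 0], collapse = ", "))
  cpm <- sweep(counts, 2, libsize, "/") * 1e6
  keep <- rowMeans(cpm >= min_cpm) >= min_fraction
  if (!any(keep)) stopf("low-expression filter removed every gene")
  counts[keep, , drop = FALSE]
}

#' GC-stratified within-sample adjustment plus between-sample quantile
#' normalization
#'
#' Stage 1 removes the GC-content effect within each sample: genes are binned
#' into `n_gc_bins` GC quantile strata and each stratum's count distribution
#' is full-quantile mapped onto the sample's overall count distribution.
#' Stage 2 applies full quantile normalization across samples so that every
#' sample shares one sorted-value distribution.
#'
#' @param counts gene-by-sample count matrix (may be real-valued).
#' @param gc named per-gene GC fraction covering all genes in `counts`.
#' @param n_gc_bins number of GC strata (>= 2); default 10.
#' @return a non-negative real-valued matrix with the dimensions of `counts`.
#' @export
gc_quantile_normalize <- function(counts, gc, n_gc_bins = 10L) {
  if (n_gc_bins < 2) stopf("n_gc_bins must be >= 2")
  if (is.null(names(gc))) stopf("gc must be named by gene")
  missing <- setdiff(rownames(counts), names(gc))
  if (length(missing)) stopf("gc content missing for %d gene(s)", length(missing))
  gc <- gc[rownames(counts)]
  breaks <- unique(stats::quantile(gc, probs = seq(0, 1, length.out = n_gc_bins + 1)))
  bin <- cut(gc, breaks = breaks, include.lowest = TRUE)
  sizes <- table(bin)
  if (any(sizes < 2)) {
    stopf("a GC bin has fewer than 2 genes; use fewer bins (n_gc_bins = %d)",
          n_gc_bins)
  }
  adjusted <- counts
  for (s in seq_len(ncol(counts))) {
    x_all <- counts[, s]
    for (b in levels(bin)) {
      sel <- bin == b
      x <- counts[sel, s]
      p <- (rank(x, ties.method = "average") - 0.5) / length(x)
      adjusted[sel, s] <- stats::quantile(x_all, probs = p, names = FALSE,
                                          type = 7)
    }
  }
  ## stage 2: full quantile normalization; every sample receives the mean
  ## sorted distribution (stable ordering resolves ties deterministically),
  ## so sorted columns are identical across samples by construction
  ref <- rowMeans(apply(adjusted, 2, sort))
  out <- adjusted
  for (s in seq_len(ncol(adjusted))) {
    out[order(adjusted[, s]), s] <- ref
  }
  dimnames(out) <- dimnames(counts)
  pmax(out, 0)
}

#' log2 counts-per-million with offset
#'
#' `log2(1e6 * count / library_size + offset)`. With the default offset 0.25
#' a zero count maps to `log2(0.25) = -2`, the floor of the log-expression
#' scale.
#'
#' @param counts gene-by-sample matrix of (possibly normalized, real-valued)
#'   counts with positive column sums.
#' @param offset added to CPM before the log; default 0.25.
#' @return gene-by-sample log2-expression matrix.
#' @export
log_cpm <- function(counts, offset = 0.25) {
  libsize <- colSums(counts)
  if (any(libsize <= 0)) stopf("zero library size in sample(s): %s",
                               paste(colnames(counts)[libsize <= 0], collapse = ", "))
  log2(sweep(counts, 2, libsize, "/") * 1e6 + offset)
}

#' Remove outlier samples by principal component analysis
#'
#' Samples are projected on the first two principal components of the
#' gene-centered matrix; a sample is an outlier when its Euclidean distance
#' from the component-space centroid exceeds `sd_threshold` times the
#' root-mean-square distance. Single pass, no iteration.
#'
#' @param expr gene-by-sample log-expression matrix with >= 3 samples.
#' @param sd_threshold multiplier of the RMS distance; default 3.
#' @return character vector of retained sample ids.
#' @export
pca_outlier_removal <- function(expr, sd_threshold = 3) {
  if (ncol(expr) < 3) stopf("need at least 3 samples for PCA outlier removal")
  x <- t(expr - rowMeans(expr))
  keep_var <- apply(x, 2, function(v) any(v != v[1]))
  sv <- svd(x[, keep_var, drop = FALSE], nu = 2, nv = 0)
  scores <- sv$u %*% diag(sv$d[1:2], nrow = 2)
  centroid <- colMeans(scores)
  d <- sqrt(rowSums(sweep(scores, 2, centroid)^2))
  rms <- sqrt(mean(d^2))
  if (rms == 0) return(colnames(expr))
  retained <- colnames(expr)[d <= sd_threshold * rms]
  if (length(retained) < 3) stopf("fewer than 3 samples remain after outlier removal")
  retained
}

#' Drop duplicated samples and small batches
#'
#' Removes duplicate sample ids (keeping the first occurrence) and every
#' sample belonging to a batch of size `<= min_batch_size - 1` (default rule:
#' batches of 4 or fewer samples are dropped; batches of exactly
#' `min_batch_size` are retained).
#'
#' @param metadata data.frame with `sample_id` and `batch`.
#' @param min_batch_size smallest batch size retained; default 5.
#' @return character vector of retained sample ids.
#' @export
remove_small_batches <- function(metadata, min_batch_size = 5L) {
  if (!all(c("sample_id", "batch") %in% names(metadata))) {
    stopf("metadata must have sample_id and batch columns")
  }
  metadata <- metadata[!duplicated(metadata$sample_id), , drop = FALSE]
  sizes <- table(metadata$batch)
  keep_batches <- names(sizes)[sizes >= min_batch_size]
  retained <- metadata$sample_id[metadata$batch %in% keep_batches]
  if (length(retained) == 0L) stopf("all samples dropped by batch-size rule")
  retained
}

#' Empirical-Bayes batch correction (ComBat)
#'
#' Location/scale batch adjustment with parametric priors: per-gene
#' standardization, per-batch location and scale estimates shrunk toward
#' batch-level moment-matched priors by iterated conditional updates, then
#' back-transformation. Supervised only on batch (no covariates). Delegates
#' to the reference implementation in the sva package. Genes without
#' residual variance are left unadjusted with a warning instead of
#' propagating a degenerate scale estimate.
#'
#' @param expr gene-by-sample log-expression matrix.
#' @param batch per-sample batch labels (length `ncol(expr)`).
#' @return adjusted matrix with the same dimensions.
#' @export
combat_adjust <- function(expr, batch) {
  batch <- as.character(batch)
  if (length(batch) != ncol(expr)) stopf("batch labels must match samples")
  if (length(unique(batch)) < 2) {
    warnf("single batch: returning input unchanged")
    return(expr)
  }
  sizes <- table(batch)
  if (any(sizes < 2)) stopf("every batch needs >= 2 samples")
  ## guard degenerate genes: zero variance overall or within some batch
  v_ok <- apply(expr, 1, stats::var) > 0
  within_ok <- rep(TRUE, nrow(expr))
  for (b in unique(batch)) {
    vb <- apply(expr[, batch == b, drop = FALSE], 1, stats::var)
    within_ok <- within_ok & vb > .Machine$double.eps
  }
  adjustable <- v_ok & within_ok
  if (!all(adjustable)) {
    warnf("%d gene(s) without within-batch variance left unadjusted",
          sum(!adjustable))
  }
  out <- expr
  if (any(adjustable)) {
    out[adjustable, ] <- suppressMessages(
      sva::ComBat(dat = expr[adjustable, , drop = FALSE],
                  batch = batch, mod = NULL,
                  par.prior = TRUE, prior.plots = FALSE))
  }
  out
}

#' Exclude small molecular subtypes
#'
#' Tumor samples belonging to a subtype (within its cancer type) with fewer
#' than `min_subtype_size` tumor members are removed. Normal samples are
#' always retained: they serve as the reference group in the relative-effect
#' comparisons.
#'
#' @param metadata data.frame with `sample_id`, `cancer_type`, `subtype`,
#'   `is_tumor`.
#' @param min_subtype_size smallest subtype retained; default 10.
#' @return character vector of retained sample ids.
#' @export
filter_small_subtypes <- function(metadata, min_subtype_size = 10L) {
  if (!all(c("sample_id", "subtype", "is_tumor") %in% names(metadata))) {
    stopf("metadata must have sample_id, subtype and is_tumor columns")
  }
  ct <- metadata$cancer_type %||% rep("", nrow(metadata))
  key <- paste(ct, metadata$subtype, sep = "::")
  tumor <- metadata$is_tumor == 1L
  sizes <- table(key[tumor])
  small <- names(sizes)[sizes < min_subtype_size]
  drop <- tumor & key %in% small
  metadata$sample_id[!drop]
}

#' Run the full expression preprocessing chain for one cancer type
#'
#' Fixed stage order: low-expression filter, GC-stratified plus
#' between-sample quantile normalization, log2-CPM transform, PCA outlier
#' removal, duplicate/small-batch removal, ComBat batch correction,
#' small-subtype exclusion.
#'
#' @param counts gene-by-sample raw counts for one cancer type.
#' @param gc named per-gene GC content.
#' @param metadata metadata rows for these samples.
#' @param min_cpm,min_fraction see [filter_low_expression()].
#' @param n_gc_bins see [gc_quantile_normalize()].
#' @param log_offset see [log_cpm()].
#' @param sd_threshold see [pca_outlier_removal()].
#' @param min_batch_size see [remove_small_batches()].
#' @param min_subtype_size see [filter_small_subtypes()].
#' @return list with `expr` (log2 scale, batch-corrected), `metadata`
#'   (retained samples) and `log` (per-stage parameter and dimension record).
#' @export
preprocess_expression <- function(counts, gc, metadata,
                                  min_cpm = 1, min_fraction = 0.2,
                                  n_gc_bins = 10L, log_offset = 0.25,
                                  sd_threshold = 3, min_batch_size = 5L,
                                  min_subtype_size = 10L) {
  log_lines <- c(sprintf("input: %d genes x %d samples", nrow(counts), ncol(counts)))
  counts <- filter_low_expression(counts, min_cpm, min_fraction)
  log_lines <- c(log_lines, sprintf(
    "filter_low_expression: min_cpm=%g min_fraction=%g -> %d genes",
    min_cpm, min_fraction, nrow(counts)))
  norm <- gc_quantile_normalize(counts, gc, n_gc_bins)
  log_lines <- c(log_lines, sprintf("gc_quantile_normalize: n_gc_bins=%d", n_gc_bins))
  expr <- log_cpm(norm, log_offset)
  log_lines <- c(log_lines, sprintf("log_cpm: offset=%g", log_offset))
  kept <- pca_outlier_removal(expr, sd_threshold)
  log_lines <- c(log_lines, sprintf(
    "pca_outlier_removal: sd_threshold=%g -> %d samples", sd_threshold, length(kept)))
  metadata <- metadata[metadata$sample_id %in% kept, , drop = FALSE]
  kept <- remove_small_batches(metadata, min_batch_size)
  log_lines <- c(log_lines, sprintf(
    "remove_small_batches: min_batch_size=%d -> %d samples",
    min_batch_size, length(kept)))
  metadata <- metadata[metadata$sample_id %in% kept, , drop = FALSE]
  expr <- expr[, metadata$sample_id, drop = FALSE]
  expr <- suppressWarnings(combat_adjust(expr, metadata$batch))
  log_lines <- c(log_lines, sprintf("combat_adjust: %d batches",
                                    length(unique(metadata$batch))))
  kept <- filter_small_subtypes(metadata, min_subtype_size)
  log_lines <- c(log_lines, sprintf(
    "filter_small_subtypes: min_subtype_size=%d -> %d samples",
    min_subtype_size, length(kept)))
  metadata <- metadata[metadata$sample_id %in% kept, , drop = FALSE]
  expr <- expr[, metadata$sample_id, drop = FALSE]
  list(expr = expr, metadata = metadata, log = log_lines)
}
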