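#' Generate a synthetic multi-cancer cohort
#'
#' Draws a full cohort — RNA-seq counts, methylation betas, cell-type
#' reference profiles, sample metadata, a gene panel annotation, a nonsilent
#' mutation table and the ground truth — with the statistical structure the
#' downstream analysis assumes:
#'
#' * counts are negative-binomial, `mu = libsize_s * q_gs` with
#'   `log2 q_gs = baseline_g + batchshift_gb + gcbias_s * (gc_g - mean(gc)) +
#'   immune_beta * immunefrac_s [immune-driven genes] + archetype shift
#'   [MHC-class genes, tumor samples]`;
#' * betas are convex mixtures of cell-type methylation profiles (epithelial,
#'   fibroblast and an immune compartment split into CD4T/CD8T) plus
#'   truncated Gaussian noise;
#' * per-sample CD4/CD8 T-cell levels are the CD4T/CD8T mixing weights, i.e.
#'   deterministic functions of the latent immune fraction;
#' * nonsilent mutations are Bernoulli per sample x gene with subtype-level
#'   rate multipliers (archetype-linked, so immune-hot subtypes carry higher
#'   burden).
#'
#' @param config a [cohort_config()].
#' @return a list of class `"cohort"` with elements `counts`, `gc`, `betas`,
#'   `reference` (3 cell types), `tcell_reference` (epithelial, fibroblast,
#'   CD4T, CD8T), `metadata`, `panel`, `mutations` and `truth`.
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  set.seed(config$seed)
  comp <- config$mhc_composition

  ## ---- samples -----------------------------------------------------------
  meta_rows <- list()
  for (i in seq_len(nrow(comp))) {
    n <- config$samples_per_subtype
    meta_rows[[length(meta_rows) + 1L]] <- data.frame(
      cancer_type = comp$cancer_type[i], subtype = comp$subtype[i],
      is_tumor = 1L, idx = seq_len(n), stringsAsFactors = FALSE)
  }
  for (ct in unique(comp$cancer_type)) {
    meta_rows[[length(meta_rows) + 1L]] <- data.frame(
      cancer_type = ct, subtype = "normal", is_tumor = 0L,
      idx = seq_len(config$n_normal_per_type), stringsAsFactors = FALSE)
  }
  metadata <- do.call(rbind, meta_rows)
  metadata <- metadata[order(metadata$cancer_type), , drop = FALSE]
  metadata$sample_id <- sprintf("%s_%s_%02d", metadata$cancer_type,
                                gsub("[^A-Za-z0-9]", "", metadata$subtype),
                                metadata$idx)
  metadata$idx <- NULL
  ## batches assigned at random within each cancer type
  metadata$batch <- NA_character_
  for (ct in unique(metadata$cancer_type)) {
    sel <- metadata$cancer_type == ct
    metadata$batch[sel] <- sprintf("%s_b%d", ct,
                                   sample.int(config$n_batches, sum(sel),
                                              replace = TRUE))
  }
  metadata <- metadata[, c("sample_id", "cancer_type", "subtype", "is_tumor",
                           "batch")]
  rownames(metadata) <- NULL
  n_samples <- nrow(metadata)

  ## ---- genes and panel ---------------------------------------------------
  spec <- config$panel_spec[config$panel_spec > 0]
  panel <- data.frame(
    gene_id = unlist(lapply(names(spec), function(cl)
      sprintf("%s%03d", cl, seq_len(spec[[cl]])))),
    class = rep(names(spec), times = spec),
    stringsAsFactors = FALSE)
  bg_ids <- sprintf("BG%04d", seq_len(config$n_genes_background))
  gene_ids <- c(panel$gene_id, bg_ids)
  n_genes <- length(gene_ids)

  baseline <- stats::rnorm(n_genes, mean = 5, sd = 1.8)
  silent <- stats::runif(n_genes) < config$low_expr_frac
  baseline[silent] <- stats::rnorm(sum(silent), mean = -4, sd = 1)
  names(baseline) <- gene_ids

  gc <- stats::runif(n_genes, 0.35, 0.65)
  names(gc) <- gene_ids

  immune_driven <- rep(FALSE, n_genes)
  n_panel <- nrow(panel)
  immune_driven[sample.int(n_panel, round(config$frac_immune_driven * n_panel))] <- TRUE
  names(immune_driven) <- gene_ids

  ## ---- latent cell fractions and T-cell split ----------------------------
  ## broad inter-tumor spread of infiltration (immune fraction mean ~0.21,
  ## sd ~0.18), so immune-driven genes carry a detectable planted correlation
  alpha <- c(epithelial = 2.4, fibroblast = 0.9, immune = 0.9)
  g <- matrix(stats::rgamma(n_samples * 3, shape = rep(alpha, each = n_samples)),
              nrow = n_samples)
  fractions <- g / rowSums(g)
  colnames(fractions) <- names(alpha)
  rownames(fractions) <- metadata$sample_id
  cd4_share <- stats::rbeta(n_samples, 6, 4)
  tcell <- cbind(TCD4 = cd4_share * fractions[, "immune"],
                 TCD8 = (1 - cd4_share) * fractions[, "immune"])
  rownames(tcell) <- metadata$sample_id

  ## ---- expression --------------------------------------------------------
  batch_levels <- sort(unique(metadata$batch))
  batch_shift <- matrix(stats::rnorm(n_genes * length(batch_levels),
                                     sd = config$batch_sd),
                        nrow = n_genes,
                        dimnames = list(gene_ids, batch_levels))
  gcbias <- stats::rnorm(n_samples, sd = config$gc_bias_sd)
  libsize <- exp(stats::rnorm(n_samples, config$libsize_log_mean,
                              config$libsize_log_sd))

  arch_of <- stats::setNames(comp$archetype,
                             paste(comp$cancer_type, comp$subtype, sep = "::"))
  sample_arch <- arch_of[paste(metadata$cancer_type, metadata$subtype,
                               sep = "::")]
  mhc_shift <- ifelse(metadata$is_tumor == 1L,
                      config$archetype_shift[sample_arch], 0)
  mhc_shift[is.na(mhc_shift)] <- 0
  is_mhc_gene <- gene_ids %in% panel$gene_id[panel$class == "MHC"]

  log2q <- matrix(baseline, nrow = n_genes, ncol = n_samples,
                  dimnames = list(gene_ids, metadata$sample_id))
  log2q <- log2q + batch_shift[, metadata$batch, drop = FALSE]
  log2q <- log2q + (gc - mean(gc)) %o% gcbias
  log2q[immune_driven, ] <- log2q[immune_driven, , drop = FALSE] +
    rep(config$immune_beta * fractions[, "immune"],
        each = sum(immune_driven))
  log2q[is_mhc_gene, ] <- log2q[is_mhc_gene, , drop = FALSE] +
    rep(mhc_shift, each = sum(is_mhc_gene))

  q <- 2^log2q
  q <- sweep(q, 2, colSums(q), "/")
  mu <- sweep(q, 2, libsize, "*")
  counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                  size = 1 / config$nb_dispersion),
                   nrow = n_genes, dimnames = dimnames(mu))

  ## ---- methylation -------------------------------------------------------
  ref <- make_reference_profiles(config$n_cpgs)
  frac4 <- cbind(epithelial = fractions[, "epithelial"],
                 fibroblast = fractions[, "fibroblast"],
                 CD4T = tcell[, "TCD4"], CD8T = tcell[, "TCD8"])
  betas <- ref$tcell %*% t(frac4)
  if (config$beta_noise_sd > 0) {
    betas <- betas + matrix(stats::rnorm(length(betas),
                                         sd = config$beta_noise_sd),
                            nrow = nrow(betas))
  }
  betas <- pmin(pmax(betas, 0), 1)
  dimnames(betas) <- list(rownames(ref$tcell), metadata$sample_id)

  ## ---- mutations ---------------------------------------------------------
  arch_mult <- c(low = 1, intermediate = 1.5, high = 3)
  sub_key <- paste(comp$cancer_type, comp$subtype, sep = "::")
  sub_mult <- stats::setNames(
    arch_mult[comp$archetype] * exp(stats::rnorm(nrow(comp), sd = 0.3)),
    sub_key)
  tumor <- metadata$is_tumor == 1L
  tumor_ids <- metadata$sample_id[tumor]
  rate <- config$mut_rate_per_gene *
    sub_mult[paste(metadata$cancer_type, metadata$subtype, sep = "::")[tumor]]
  hit <- matrix(stats::runif(length(tumor_ids) * n_genes), nrow = n_genes) <
    rep(pmin(rate, 1), each = n_genes)
  idx <- which(hit, arr.ind = TRUE)
  classes <- maf_nonsilent_classes()
  mutations <- data.frame(
    sample_id = tumor_ids[idx[, 2]],
    gene = gene_ids[idx[, 1]],
    variant_class = sample(classes, nrow(idx), replace = TRUE,
                           prob = c(0.6, 0.1, 0.08, 0.07, 0.03, 0.03, 0.06,
                                    0.01, 0.02)),
    stringsAsFactors = FALSE)
  mutations <- mutations[order(mutations$sample_id, mutations$gene), ,
                         drop = FALSE]
  rownames(mutations) <- NULL

  truth <- list(fractions = fractions, tcell = tcell,
                archetype = comp,
                immune_driven = immune_driven,
                baseline = baseline, batch_shift = batch_shift,
                gc_bias = stats::setNames(gcbias, metadata$sample_id),
                libsize = stats::setNames(libsize, metadata$sample_id),
                subtype_mut_mult = sub_mult)

  structure(list(counts = counts, gc = gc, betas = betas,
                 reference = ref$bulk, tcell_reference = ref$tcell,
                 metadata = metadata, panel = panel, mutations = mutations,
                 truth = truth, config = config),
            class = "cohort")
}

#' Build synthetic cell-type methylation reference profiles
#'
#' Each CpG discriminates one of four cell types (epithelial, fibroblast,
#' CD4T, CD8T): near-1 beta in its target type and near-0 elsewhere, the way
#' reference panels for methylation deconvolution are constructed. The bulk
#' (3-type) reference collapses CD4T/CD8T into an immune profile as their
#' exact mean.
#'
#' @param n_cpgs number of CpGs.
#' @return list with `bulk` (CpG x {epithelial, fibroblast, immune}) and
#'   `tcell` (CpG x {epithelial, fibroblast, CD4T, CD8T}) matrices.
#' @keywords internal
make_reference_profiles <- function(n_cpgs) {
  cpg_ids <- sprintf("cg%06d", seq_len(n_cpgs))
  types <- c("epithelial", "fibroblast", "CD4T", "CD8T")
  target <- rep_len(types, n_cpgs)
  tcell <- matrix(stats::runif(n_cpgs * 4, 0.03, 0.2), nrow = n_cpgs,
                  dimnames = list(cpg_ids, types))
  for (k in seq_along(types)) {
    sel <- target == types[k]
    tcell[sel, k] <- stats::runif(sum(sel), 0.8, 0.97)
  }
  bulk <- cbind(epithelial = tcell[, "epithelial"],
                fibroblast = tcell[, "fibroblast"],
                immune = (tcell[, "CD4T"] + tcell[, "CD8T"]) / 2)
  list(bulk = bulk, tcell = tcell)
}

#' @export
print.cohort <- function(x, ...) {
  cat("Synthetic cohort:",
      nrow(x$counts), "genes x", ncol(x$counts), "samples;",
      nrow(x$betas), "CpGs;",
      length(unique(x$metadata$cancer_type)), "cancer types;",
      sum(x$metadata$is_tumor == 1L), "tumors /",
      sum(x$metadata$is_tumor == 0L), "normals\n")
  invisible(x)
}
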