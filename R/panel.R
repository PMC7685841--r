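#' Spearman correlation with BH-adjusted p-values
#'
#' Midrank-tie Spearman rho of every row of `x` against `y`, two-sided
#' p-values from the t approximation, and Benjamini-Hochberg q-values across
#' the variables tested. Zero-variance variables get rho 0 and q 1 with a
#' warning.
#'
#' @param x variable-by-sample numeric matrix.
#' @param y numeric vector, one value per sample.
#' @return data.frame with `variable`, `rho`, `p`, `q`.
#' @export
spearman_fdr <- function(x, y) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  n <- ncol(x)
  if (n < 3) stopf("need >= 3 samples")
  if (length(y) != n || !all(is.finite(y))) stopf("y must be finite, one value per sample")
  ry <- rank(y)
  rx <- t(apply(x, 1, rank))
  sd_x <- apply(rx, 1, stats::sd)
  degenerate <- sd_x == 0 | stats::sd(ry) == 0
  rho <- rep(0, nrow(x))
  ok <- !degenerate
  if (any(ok)) {
    rho[ok] <- drop(stats::cor(ry, t(rx[ok, , drop = FALSE])))
  }
  if (any(degenerate)) warnf("%d zero-variance variable(s): rho set to 0, q to 1",
                             sum(degenerate))
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(rho) >= 1 - 1e-12] <- 0
  p[degenerate] <- 1
  q <- stats::p.adjust(p, method = "BH")
  q[degenerate] <- 1
  data.frame(variable = rownames(x) %||% paste0("v", seq_len(nrow(x))),
             rho = rho, p = p, q = q, stringsAsFactors = FALSE)
}

#' Flag panel genes lowly expressed in any subtype
#'
#' A panel gene is flagged when its median log2-CPM within any tumor subtype
#' of any cancer type falls below `min_median_logcpm` (the "at least one
#' subtype" rule), or when it is absent from the expression matrix of some
#' cancer type (removed upstream by the low-expression filter).
#'
#' @param expr_by_type named list (per cancer type) of gene-by-sample
#'   log-expression matrices.
#' @param metadata sample metadata covering all samples in `expr_by_type`.
#' @param panel data.frame with `gene_id`, `class`.
#' @param min_median_logcpm threshold; default 0 (median CPM of about 1).
#' @return character vector of flagged gene ids.
#' @export
flag_low_expressed_panel <- function(expr_by_type, metadata, panel,
                                     min_median_logcpm = 0) {
  flagged <- character()
  for (ct in names(expr_by_type)) {
    expr <- expr_by_type[[ct]]
    absent <- setdiff(panel$gene_id, rownames(expr))
    flagged <- union(flagged, absent)
    md <- metadata[match(colnames(expr), metadata$sample_id), , drop = FALSE]
    present <- intersect(panel$gene_id, rownames(expr))
    for (st in unique(md$subtype[md$is_tumor == 1L])) {
      cols <- md$sample_id[md$subtype == st & md$is_tumor == 1L]
      med <- apply(expr[present, cols, drop = FALSE], 1, stats::median)
      flagged <- union(flagged, present[med < min_median_logcpm])
    }
  }
  flagged
}

#' Remove panel genes correlated with immune infiltration
#'
#' Within each cancer type (tumor samples only), a panel gene is
#' removal-flagged when its Spearman correlation with the estimated immune
#' fraction is strong (`rho >= r_threshold` in `"positive"` mode,
#' `|rho| >= r_threshold` in `"absolute"` mode; the threshold is inclusive)
#' and significant (`q <= fdr`, BH across panel genes within the type). A
#' gene flagged in any cancer type is removed from the global panel.
#'
#' @param expr_by_type named list (per cancer type) of gene-by-sample
#'   log-expression matrices (tumor samples only, or mixed: tumors are
#'   selected via `metadata`).
#' @param immune_fraction named per-sample immune fraction estimates.
#' @param metadata sample metadata.
#' @param panel data.frame with `gene_id`, `class`.
#' @param r_threshold correlation threshold; default 0.4.
#' @param fdr FDR threshold; default 0.05.
#' @param mode `"positive"` (default) or `"absolute"`.
#' @return list with `panel` (retained panel data.frame) and `report`
#'   (per-type data.frame of gene, cancer_type, rho, q, flagged).
#' @export
immune_correlation_filter <- function(expr_by_type, immune_fraction, metadata,
                                      panel, r_threshold = 0.4, fdr = 0.05,
                                      mode = c("positive", "absolute")) {
  mode <- match.arg(mode)
  reports <- list()
  removed <- character()
  for (ct in names(expr_by_type)) {
    expr <- expr_by_type[[ct]]
    md <- metadata[match(colnames(expr), metadata$sample_id), , drop = FALSE]
    cols <- md$sample_id[md$is_tumor == 1L]
    cols <- intersect(cols, names(immune_fraction))
    genes <- intersect(panel$gene_id, rownames(expr))
    if (length(cols) < 3 || length(genes) == 0) next
    res <- suppressWarnings(
      spearman_fdr(expr[genes, cols, drop = FALSE], immune_fraction[cols]))
    strong <- if (mode == "positive") res$rho >= r_threshold else abs(res$rho) >= r_threshold
    res$flagged <- strong & res$q <= fdr
    res$cancer_type <- ct
    reports[[ct]] <- res
    removed <- union(removed, res$variable[res$flagged])
  }
  report <- do.call(rbind, reports)
  rownames(report) <- NULL
  list(panel = panel[!panel$gene_id %in% removed, , drop = FALSE],
       report = report, removed = removed)
}

#' Pan-cancer signed correlation summary
#'
#' Within each cancer type, all pairwise Spearman correlations among the
#' supplied variables (retained panel genes plus T-cell levels) are tested
#' with BH-FDR across pairs; a pair with `|rho| >= r_threshold` and
#' `q <= fdr` contributes `sign(rho)` for that type. The summary matrix is
#' the elementwise sum over cancer types, so each entry is bounded by plus or
#' minus the number of types. Variables missing in a type contribute 0 for
#' all their pairs in that type.
#'
#' @param vars_by_type named list (per cancer type) of variable-by-sample
#'   matrices.
#' @param r_threshold,fdr thresholds as in [immune_correlation_filter()].
#' @return list with `summary` (symmetric integer matrix, diagonal `NA`) and
#'   `n_types` used.
#' @export
pan_cancer_correlation_summary <- function(vars_by_type, r_threshold = 0.4,
                                           fdr = 0.05) {
  if (length(vars_by_type) < 2) stopf("need >= 2 cancer types")
  all_vars <- Reduce(union, lapply(vars_by_type, rownames))
  S <- matrix(0L, length(all_vars), length(all_vars),
              dimnames = list(all_vars, all_vars))
  for (ct in names(vars_by_type)) {
    m <- vars_by_type[[ct]]
    n <- ncol(m)
    if (n < 3) next
    rx <- t(apply(m, 1, rank))
    sds <- apply(rx, 1, stats::sd)
    keep <- sds > 0
    rx <- rx[keep, , drop = FALSE]
    v <- nrow(rx)
    if (v < 2) next
    R <- stats::cor(t(rx))
    tstat <- R * sqrt((n - 2) / pmax(1 - R^2, .Machine$double.eps))
    P <- 2 * stats::pt(-abs(tstat), df = n - 2)
    P[abs(R) >= 1 - 1e-12] <- 0
    ut <- upper.tri(R)
    q <- stats::p.adjust(P[ut], method = "BH")
    Q <- matrix(1, v, v); Q[ut] <- q; Q <- pmin(Q, t(Q))
    sig <- abs(R) >= r_threshold & Q <= fdr & ut
    contrib <- matrix(0L, v, v)
    contrib[sig] <- as.integer(sign(R[sig]))
    contrib <- contrib + t(contrib)
    ids <- rownames(rx)
    S[ids, ids] <- S[ids, ids] + contrib
  }
  diag(S) <- NA_integer_
  list(summary = S, n_types = length(vars_by_type))
}
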