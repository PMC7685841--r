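#' Reference-based methylation deconvolution by robust partial correlations
#'
#' For each sample, fits the methylation beta vector (restricted to CpGs
#' shared with the reference) on the cell-type reference profiles by robust
#' linear regression with Huber M-estimation (iteratively reweighted least
#' squares, no intercept: betas and reference live on the same [0,1] scale).
#' Negative coefficients are truncated to zero and the remainder renormalized
#' to the unit simplex — the RPC recipe for reference-based cell-fraction
#' inference.
#'
#' @param betas CpG-by-sample matrix in [0,1].
#' @param reference CpG-by-cell-type matrix in [0,1] (>= 2 cell types).
#' @param huber_c Huber tuning constant; default 1.345. As `huber_c` grows
#'   the fit converges to ordinary least squares followed by truncation.
#' @param max_iter IRLS iteration cap; default 50.
#' @return sample-by-cell-type matrix of fractions; rows sum to 1.
#' @export
rpc_deconvolve <- function(betas, reference, huber_c = 1.345, max_iter = 50L) {
  if (!all(is.finite(betas))) stopf("betas contain non-finite values")
  if (ncol(reference) < 2) stopf("reference needs >= 2 cell types")
  shared <- intersect(rownames(betas), rownames(reference))
  if (length(shared) == 0L) stopf("no shared CpGs between betas and reference")
  if (length(shared) < 50L) {
    warnf("only %d shared CpGs between betas and reference", length(shared))
  }
  X <- reference[shared, , drop = FALSE]
  Y <- betas[shared, , drop = FALSE]
  collinear <- qr(X)$rank < ncol(X)
  if (collinear) {
    warnf("reference profiles are collinear; using minimum-norm least squares")
    Xg <- MASS::ginv(X)
  }
  out <- matrix(NA_real_, nrow = ncol(Y), ncol = ncol(X),
                dimnames = list(colnames(Y), colnames(X)))
  for (s in seq_len(ncol(Y))) {
    coefs <- if (collinear) {
      drop(Xg %*% Y[, s])
    } else {
      fit <- suppressWarnings(
        MASS::rlm(X, Y[, s], psi = MASS::psi.huber, k = huber_c,
                  maxit = max_iter, acc = 1e-6))
      stats::coef(fit)
    }
    coefs[!is.finite(coefs)] <- 0
    coefs <- pmax(coefs, 0)
    if (sum(coefs) == 0) {
      warnf("all coefficients non-positive for sample %s; uniform fractions",
            colnames(Y)[s])
      coefs <- rep(1, length(coefs))
    }
    out[s, ] <- coefs / sum(coefs)
  }
  out
}

#' Infer CD4/CD8 T-cell levels from methylation
#'
#' Runs [rpc_deconvolve()] against a reference that resolves the immune
#' compartment into CD4T and CD8T profiles and returns the CD4T/CD8T columns
#' of the simplex fit, without renormalizing after extraction (levels are
#' fractions of the whole sample, not of the T-cell compartment).
#'
#' @param betas CpG-by-sample matrix.
#' @param tcell_reference CpG-by-cell-type reference containing columns
#'   `CD4T` and `CD8T` (plus any other cell types).
#' @param ... passed to [rpc_deconvolve()].
#' @return sample-by-2 matrix with columns `CD4T`, `CD8T`.
#' @export
infer_tcell_levels <- function(betas, tcell_reference, ...) {
  if (!all(c("CD4T", "CD8T") %in% colnames(tcell_reference))) {
    stopf("tcell_reference must contain CD4T and CD8T profiles")
  }
  fr <- rpc_deconvolve(betas, tcell_reference, ...)
  fr[, c("CD4T", "CD8T"), drop = FALSE]
}
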