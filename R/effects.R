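#' Nonparametric relative effects by midranks
#'
#' For each variable, the relative effect of group i is the probability that
#' a randomly drawn observation from the reference distribution is smaller
#' than (plus half the probability of being tied with) an observation from
#' group i; 0.5 means no shift. Two estimators:
#'
#' * `weighted` (default): pooled-midrank estimator
#'   `p_i = (mean midrank of group i - 0.5) / N` over the pooled N
#'   observations. The group-size-weighted mean of `p_i` equals 0.5 exactly
#'   (midrank identity), anchoring "not changed" at 0.5.
#' * `unweighted`: `p_i = mean_j [P(X_j < X_i) + 0.5 P(X_j = X_i)]` by
#'   pairwise comparison counts, averaging the groups equally (own group
#'   contributes exactly 0.5).
#'
#' Ties are handled by midranks / half-counts in both variants. A variable
#' constant across all samples yields 0.5 for every group.
#'
#' A third estimator anchors against a designated reference group instead of
#' the pooled sample: with `reference_group` set (e.g. `"normal"`),
#' `p_i = P(X_ref < X_i) + 0.5 P(X_ref = X_i)` by pairwise counts against
#' that group only, so 0.5 means "not changed relative to the reference
#' group" regardless of how the remaining groups are composed. The reference
#' group itself gets exactly 0.5.
#'
#' @param values variable-by-sample numeric matrix (a vector is treated as
#'   one variable).
#' @param groups per-sample group labels (>= 2 groups, each >= 2 samples
#'   recommended).
#' @param variant `"weighted"` or `"unweighted"`.
#' @param reference_group optional group label; when set, effects are
#'   computed against this group's distribution only and `variant` is
#'   ignored.
#' @return list with `effects` (group-by-variable matrix in [0,1]) and
#'   `group_sizes` (named integer vector).
#' @export
midrank_relative_effects <- function(values, groups,
                                     variant = c("weighted", "unweighted"),
                                     reference_group = NULL) {
  variant <- match.arg(variant)
  if (is.vector(values)) values <- matrix(values, nrow = 1,
                                          dimnames = list("v1", NULL))
  groups <- as.character(groups)
  if (length(groups) != ncol(values)) stopf("one group label per sample required")
  glev <- unique(groups)
  if (length(glev) < 2) stopf("need >= 2 groups")
  N <- ncol(values)
  eff <- matrix(NA_real_, nrow = length(glev), ncol = nrow(values),
                dimnames = list(glev, rownames(values)))
  gi <- split(seq_len(N), factor(groups, levels = glev))
  if (!is.null(reference_group)) {
    if (!reference_group %in% glev) stopf("reference group '%s' absent",
                                          reference_group)
    for (v in seq_len(nrow(values))) {
      x <- values[v, ]
      xr <- sort(x[gi[[reference_group]]])
      nr <- length(xr)
      for (g in glev) {
        xi <- x[gi[[g]]]
        below <- findInterval(xi, xr, left.open = TRUE)   # #{ref < xi}
        upto <- findInterval(xi, xr)                      # #{ref <= xi}
        eff[g, v] <- mean((below + 0.5 * (upto - below)) / nr)
      }
    }
    return(list(effects = eff, group_sizes = vapply(gi, length, integer(1))))
  }
  for (v in seq_len(nrow(values))) {
    x <- values[v, ]
    if (variant == "weighted") {
      r <- rank(x, ties.method = "average")
      for (g in glev) eff[g, v] <- (mean(r[gi[[g]]]) - 0.5) / N
    } else {
      for (g in glev) {
        xi <- x[gi[[g]]]
        pij <- vapply(glev, function(h) {
          xj <- x[gi[[h]]]
          (sum(outer(xj, xi, "<")) + 0.5 * sum(outer(xj, xi, "=="))) /
            (length(xi) * length(xj))
        }, numeric(1))
        eff[g, v] <- mean(pij)
      }
    }
  }
  list(effects = eff,
       group_sizes = vapply(gi, length, integer(1)))
}

#' Permutation ANOVA-type test on relative effects
#'
#' Test statistic `T = sum over variables sum over groups of
#' n_i (p_i - 0.5)^2`, with `p_i` the weighted (pooled-midrank) relative
#' effects. The null distribution is obtained by permuting the group labels
#' jointly across variables; `p = (1 + #{T_perm >= T_obs}) / (n_perm + 1)`.
#' Because midranks are invariant under label permutation they are computed
#' once, making the permutation loop a rank-averaging exercise.
#'
#' @param values variable-by-sample matrix.
#' @param groups per-sample group labels.
#' @param n_perm number of permutations (>= 99); default 999.
#' @param seed integer seed for the permutation draw.
#' @return list with `statistic`, `p_value`, `n_perm`.
#' @export
permutation_ats_test <- function(values, groups, n_perm = 999L, seed = 1L) {
  if (n_perm < 99) stopf("n_perm must be >= 99")
  if (is.vector(values)) values <- matrix(values, nrow = 1)
  groups <- as.character(groups)
  glev <- unique(groups)
  if (length(glev) < 2) stopf("need >= 2 groups")
  N <- ncol(values)
  R <- t(apply(values, 1, rank))          # variables x samples, fixed
  f <- factor(groups, levels = glev)
  n_g <- as.integer(table(f))
  stat_for <- function(fac) {
    ## group mean ranks per variable: variables x groups
    M <- t(rowsum(t(R), fac)) / rep(as.integer(table(fac)), each = nrow(R))
    P <- (M - 0.5) / N
    sum(sweep((P - 0.5)^2, 2, as.integer(table(fac)), "*"))
  }
  obs <- stat_for(f)
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    fp <- f[sample.int(N)]
    if (stat_for(fp) >= obs) exceed <- exceed + 1L
  }
  list(statistic = obs, p_value = (1 + exceed) / (n_perm + 1),
       n_perm = n_perm)
}

#' Subtype-by-variable relative-effect matrix across cancer types
#'
#' Within each cancer type the groups are its tumor subtypes plus the
#' literal group `"normal"`; relative effects are computed per variable
#' (panel-gene expression plus any extra per-sample variables such as
#' mutation burden and T-cell levels) against the pooled within-type
#' reference. Normal rows are dropped from the output (kept in
#' `diagnostics`) and subtype rows are concatenated across types as
#' `cancer_type::subtype`.
#'
#' @param expr_by_type named list (per cancer type) of gene-by-sample
#'   log-expression matrices restricted to the retained panel.
#' @param extra_vars optional sample-by-variable matrix (e.g. columns
#'   `MUTsum`, `TCD4`, `TCD8`) with rownames covering the samples.
#' @param metadata sample metadata.
#' @param variant passed to [midrank_relative_effects()].
#' @param reference `"normal"` (default): each subtype's probability is
#'   anchored against the normal-tissue distribution of its cancer type, so
#'   0.5 reads "not changed compared to normal adjacent tissue" irrespective
#'   of the type's subtype composition. `"pooled"`: anchored against the
#'   pooled within-type sample (the weighted-midrank estimator), whose
#'   size-weighted mean is 0.5 by construction but whose anchor shifts with
#'   the type's subtype mix.
#' @return list with `effects` (subtype-by-variable matrix; `NA` where a
#'   variable is absent for a type), `group_sizes`, `diagnostics` (normal
#'   rows), and `bands` (discretized at 0.4/0.6: `lower`, `unchanged`,
#'   `higher`).
#' @export
subtype_effect_matrix <- function(expr_by_type, extra_vars = NULL, metadata,
                                  variant = "weighted",
                                  reference = c("normal", "pooled")) {
  reference <- match.arg(reference)
  all_vars <- Reduce(union, lapply(expr_by_type, rownames))
  if (!is.null(extra_vars)) all_vars <- union(all_vars, colnames(extra_vars))
  rows <- list(); diag_rows <- list(); sizes <- integer()
  for (ct in names(expr_by_type)) {
    expr <- expr_by_type[[ct]]
    md <- metadata[match(colnames(expr), metadata$sample_id), , drop = FALSE]
    grp <- ifelse(md$is_tumor == 1L, md$subtype, "normal")
    if (sum(grp == "normal") < 2) stopf("cancer type %s has < 2 normal samples", ct)
    vals <- expr
    if (!is.null(extra_vars)) {
      ev <- t(extra_vars[md$sample_id, , drop = FALSE])
      vals <- rbind(vals, ev)
    }
    missing_vars <- setdiff(all_vars, rownames(vals))
    if (length(missing_vars)) {
      message(sprintf("cancer type %s: %d variable(s) absent, set to NA",
                      ct, length(missing_vars)))
    }
    re <- midrank_relative_effects(
      vals, grp, variant = variant,
      reference_group = if (reference == "normal") "normal" else NULL)
    eff <- matrix(NA_real_, nrow = nrow(re$effects), ncol = length(all_vars),
                  dimnames = list(rownames(re$effects), all_vars))
    eff[, colnames(re$effects)] <- re$effects
    tumor_rows <- setdiff(rownames(eff), "normal")
    blk <- eff[tumor_rows, , drop = FALSE]
    rownames(blk) <- paste(ct, tumor_rows, sep = "::")
    rows[[ct]] <- blk
    diag_rows[[ct]] <- eff["normal", , drop = FALSE]
    sz <- re$group_sizes[tumor_rows]
    names(sz) <- paste(ct, tumor_rows, sep = "::")
    sizes <- c(sizes, sz)
  }
  effects <- do.call(rbind, rows)
  bands <- matrix(ifelse(effects <= 0.4, "lower",
                         ifelse(effects >= 0.6, "higher", "unchanged")),
                  nrow = nrow(effects), dimnames = dimnames(effects))
  list(effects = effects, group_sizes = sizes,
       diagnostics = do.call(rbind, diag_rows), bands = bands)
}
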