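# Shared fixtures and independent oracles used across the suite.

# Compact planted layout: 3 cancer types, 8 subtypes (3 low / 3 int / 2 high),
# small enough that a full pipeline run stays fast.
small_composition <- function() {
  data.frame(
    cancer_type = c("T1", "T1", "T1", "T2", "T2", "T2", "T3", "T3"),
    subtype = c("A", "B", "C", "A", "B", "C", "A", "B"),
    archetype = c("low", "intermediate", "high", "low", "intermediate",
                  "high", "low", "intermediate"),
    stringsAsFactors = FALSE)
}

small_config <- function(seed = 1L, ...) {
  cohort_config(
    mhc_composition = small_composition(),
    samples_per_subtype = 14L, n_normal_per_type = 6L,
    n_genes_background = 60L,
    panel_spec = c(CAG = 20L, immunoinhibitor = 8L, MHC = 10L, other = 0L),
    n_cpgs = 200L, seed = seed, ...)
}

# Brute-force oracle for the weighted relative effect: for each observation
# of group i, count (over ALL ordered pairs against the pooled sample,
# including the self pair) how often the pooled observation is smaller, plus
# half the ties, and average within the group.
oracle_weighted_effects <- function(x, groups) {
  N <- length(x)
  vapply(unique(groups), function(g) {
    xi <- x[groups == g]
    mean(vapply(xi, function(t) sum(x < t) + 0.5 * sum(x == t), numeric(1))) / N
  }, numeric(1))
}

# Exhaustive nonnegative least squares for a 3-column design: enumerate all
# active sets, keep the feasible solution with minimal residual.
oracle_nnls <- function(X, y) {
  p <- ncol(X)
  best <- NULL; best_rss <- Inf
  for (mask in 0:(2^p - 1)) {
    free <- which(bitwAnd(mask, 2^(seq_len(p) - 1)) > 0)
    beta <- rep(0, p)
    if (length(free) > 0) {
      fit <- tryCatch(qr.solve(X[, free, drop = FALSE], y),
                      error = function(e) NULL)
      if (is.null(fit)) next
      beta[free] <- fit
    }
    if (any(beta < -1e-12)) next
    rss <- sum((y - X %*% beta)^2)
    if (rss < best_rss - 1e-15) { best_rss <- rss; best <- beta }
  }
  best
}

# Per-gene fraction of variance explained by batch.
mean_eta_squared <- function(m, batch) {
  f <- factor(batch)
  mean(apply(m, 1, function(v) {
    gm <- tapply(v, f, mean)
    ssb <- sum(table(f) * (gm - mean(v))^2)
    sst <- sum((v - mean(v))^2)
    if (sst == 0) 0 else ssb / sst
  }))
}
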