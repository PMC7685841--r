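test_that("weighted relative effects match the brute-force pairwise oracle", {
  x <- c(1, 2, 3, 4, 5, 6)
  g <- rep(c("A", "B"), each = 3)
  eff <- midrank_relative_effects(x, g)$effects
  expect_equal(unname(eff[, 1]), c(0.25, 0.75))
  expect_equal(unname(eff[, 1]), unname(oracle_weighted_effects(x, g)))

  # identically distributed groups sit at 0.5
  eff2 <- midrank_relative_effects(c(1, 2, 1, 2), rep(c("A", "B"), each = 2))
  expect_equal(unname(eff2$effects[, 1]), c(0.5, 0.5))

  # duplicated singleton groups, ties handled by midranks; oracle-computed
  x3 <- c(1, 1, 2, 2, 3, 3)
  g3 <- rep(c("A", "B", "C"), each = 2)
  eff3 <- midrank_relative_effects(x3, g3)$effects
  expect_equal(unname(eff3[, 1]), unname(oracle_weighted_effects(x3, g3)))
  expect_equal(unname(eff3[, 1]), c(1, 3, 5) / 6)

  # randomized property: exact oracle equality for all-distinct data,
  # group sizes <= 6, and for tied data too
  set.seed(50)
  for (i in 1:25) {
    sizes <- sample(2:6, 3, replace = TRUE)
    g <- rep(c("A", "B", "C"), times = sizes)
    x <- if (i %% 2) sample(100, sum(sizes)) else sample(5, sum(sizes), TRUE)
    eff <- midrank_relative_effects(x, g)$effects[, 1]
    expect_equal(unname(eff), unname(oracle_weighted_effects(x, g)[c("A", "B", "C")]))
  }
})

test_that("group-size-weighted mean effect is exactly 0.5 (conservation)", {
  set.seed(51)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    g <- sample(letters[1:4], n, replace = TRUE)
    while (length(unique(g)) < 2) g <- sample(letters[1:4], n, replace = TRUE)
    x <- matrix(rnorm(3 * n), nrow = 3)
    if (i %% 3 == 0) x <- round(x)            # force ties
    re <- midrank_relative_effects(x, g)
    w <- re$group_sizes[rownames(re$effects)] / n
    expect_equal(unname(colSums(re$effects * w)), rep(0.5, 3),
                 tolerance = 1e-9)
  }
})

test_that("relative effects are invariant under monotone transforms and
           constant variables sit at 0.5", {
  set.seed(52)
  x <- rnorm(30)
  g <- rep(c("A", "B", "C"), each = 10)
  e1 <- midrank_relative_effects(x, g)$effects
  e2 <- midrank_relative_effects(exp(2 * x) + 5, g)$effects
  expect_equal(e1, e2)
  e3 <- midrank_relative_effects(rep(7, 30), g)$effects
  expect_true(all(e3 == 0.5))
})

test_that("unweighted variant averages groups equally", {
  # unbalanced groups: B's values all above A's and C's
  x <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 0.5, 0.6)
  g <- c(rep("A", 4), rep("B", 6), rep("C", 2))
  un <- midrank_relative_effects(x, g, variant = "unweighted")$effects[, 1]
  # oracle: mean over groups j of pairwise P(X_j < X_i) + half ties
  oracle_un <- vapply(c("A", "B", "C"), function(i) {
    xi <- x[g == i]
    mean(vapply(c("A", "B", "C"), function(j) {
      xj <- x[g == j]
      (sum(outer(xj, xi, "<")) + 0.5 * sum(outer(xj, xi, "=="))) /
        (length(xi) * length(xj))
    }, numeric(1)))
  }, numeric(1))
  expect_equal(unname(un), unname(oracle_un))
  # own-group term is exactly 0.5, so equal distributions give 0.5
  expect_equal(unname(midrank_relative_effects(
    c(1, 2, 1, 2), rep(c("A", "B"), each = 2),
    variant = "unweighted")$effects[, 1]), c(0.5, 0.5))
})

test_that("reference-group anchoring scores groups against that group only", {
  x <- c(1, 2, 3, 10, 11, 12, 1, 2, 3)
  g <- c(rep("normal", 3), rep("up", 3), rep("same", 3))
  eff <- midrank_relative_effects(x, g, reference_group = "normal")$effects[, 1]
  expect_equal(unname(eff["normal"]), 0.5)      # reference scores itself 0.5
  expect_equal(unname(eff["up"]), 1)            # entirely above the reference
  expect_equal(unname(eff["same"]), 0.5)        # copy of the reference
  # unlike the pooled anchor, adding more "up" groups does not move "same"
  x2 <- c(x, 10, 11, 12)
  g2 <- c(g, rep("up2", 3))
  eff2 <- midrank_relative_effects(x2, g2, reference_group = "normal")$effects[, 1]
  expect_equal(unname(eff2["same"]), 0.5)
  expect_error(midrank_relative_effects(x, g, reference_group = "missing"),
               "absent")
})

test_that("the permutation ANOVA-type test is calibrated, powerful and
           rank-invariant", {
  # shifted groups reach the minimum attainable p-value
  set.seed(60)
  x <- rbind(c(rnorm(10), rnorm(10, mean = 5)))
  g <- rep(c("A", "B"), each = 10)
  res <- permutation_ats_test(x, g, n_perm = 199, seed = 1)
  expect_equal(res$p_value, 1 / 200)
  # permuting sample order leaves the observed statistic unchanged
  perm <- sample(20)
  res2 <- permutation_ats_test(x[, perm, drop = FALSE], g[perm],
                               n_perm = 199, seed = 1)
  expect_equal(res2$statistic, res$statistic)
  # determinism given seed
  expect_equal(permutation_ats_test(x, g, n_perm = 199, seed = 9)$p_value,
               permutation_ats_test(x, g, n_perm = 199, seed = 9)$p_value)
  expect_error(permutation_ats_test(x, g, n_perm = 50), "99")
  expect_error(permutation_ats_test(x, rep("A", 20)), "2 groups")
})

test_that("the subtype effect matrix flags planted shifts in the right
           direction", {
  co <- generate_cohort(small_config(seed = 15))
  md <- co$metadata
  types <- unique(md$cancer_type)
  cpm <- log_cpm(co$counts)
  mhc <- co$panel$gene_id[co$panel$class == "MHC"]
  expr_by_type <- lapply(types, function(ct) {
    cpm[mhc, md$sample_id[md$cancer_type == ct], drop = FALSE]
  })
  names(expr_by_type) <- types
  mutsum <- per_sample_mutation_burden(co$mutations, sample_ids = md$sample_id)
  extra <- cbind(MUTsum = mutsum, co$truth$tcell[md$sample_id, ])
  eff <- subtype_effect_matrix(expr_by_type, extra, md)
  arch <- co$truth$archetype
  key <- paste(arch$cancer_type, arch$subtype, sep = "::")
  mean_mhc <- rowMeans(eff$effects[, mhc])
  planted <- arch$archetype[match(names(mean_mhc), key)]
  expect_lt(max(mean_mhc[planted == "low"]), 0.4)
  expect_gt(min(mean_mhc[planted == "high"]), 0.6)
  expect_true(all(mean_mhc[planted == "low"] <
                    min(mean_mhc[planted == "intermediate"])))
  # bands discretize at the documented cutpoints
  expect_true(all(eff$bands[eff$effects <= 0.4] == "lower"))
  expect_true(all(eff$bands[eff$effects >= 0.6] == "higher"))
  # normal rows live in diagnostics, not in the output
  expect_false(any(grepl("::normal$", rownames(eff$effects))))
  expect_equal(nrow(eff$diagnostics), length(types))
})
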