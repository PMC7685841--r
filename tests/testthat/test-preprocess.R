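make_counts <- function(m) {
  rownames(m) <- paste0("g", seq_len(nrow(m)))
  colnames(m) <- paste0("s", seq_len(ncol(m)))
  m
}

test_that("low-expression filter applies inclusive CPM boundaries", {
  # 10 samples, library size 1e6 so count == CPM
  m <- make_counts(matrix(50, nrow = 3, ncol = 10))
  m[1, ] <- 0                                   # all-zero gene: removed
  m[2, ] <- c(1, 1, rep(0, 8))                  # CPM >= 1 in exactly 2 of 10
  m["g3", ] <- 1e6 - colSums(m[1:2, , drop = FALSE])
  out <- filter_low_expression(m, min_cpm = 1, min_fraction = 0.2)
  expect_false("g1" %in% rownames(out))
  expect_true("g2" %in% rownames(out))          # boundary inclusive
  expect_identical(colnames(out), colnames(m))
  # min_fraction = 1 with a single zero-CPM sample: removed
  out2 <- filter_low_expression(m, min_cpm = 1, min_fraction = 1)
  expect_false("g2" %in% rownames(out2))
  expect_error(filter_low_expression(m * 0 + c(1, 0, 0), min_cpm = 1e9),
               "every gene")
})

test_that("GC/quantile normalization equalizes sample distributions and is
           identity on bin-homogeneous identical samples", {
  set.seed(1)
  # construct counts where every GC bin holds the same value multiset, so
  # the within-sample stage is exact identity; identical columns make the
  # between-sample stage identity too
  vals <- rep(c(1, 5, 10, 50, 100), times = 4)
  m <- make_counts(matrix(rep(vals, 6), ncol = 6))
  gc <- stats::setNames(rep(seq(0.35, 0.65, length.out = 4), each = 5),
                        rownames(m))
  out <- gc_quantile_normalize(m, gc, n_gc_bins = 4)
  expect_equal(out, m, tolerance = 1e-9, ignore_attr = TRUE)

  # after stage 2 every sample shares one sorted distribution
  m2 <- make_counts(matrix(rnbinom(200 * 8, mu = 60, size = 2), ncol = 8))
  gc2 <- stats::setNames(runif(200, 0.3, 0.7), rownames(m2))
  out2 <- gc_quantile_normalize(m2, gc2, n_gc_bins = 5)
  sorted <- apply(out2, 2, sort)
  expect_true(max(abs(sorted - sorted[, 1])) < 1e-9)
  expect_true(all(out2 >= 0))

  expect_error(gc_quantile_normalize(m2, gc2, n_gc_bins = 150), "fewer bins")
})

test_that("GC adjustment attenuates a planted per-sample GC trend", {
  co <- generate_cohort(small_config(seed = 9, gc_bias_sd = 1.5))
  counts <- filter_low_expression(co$counts)
  gc <- co$gc[rownames(counts)]
  # the planted bias is per sample (random sign), so measure the mean
  # magnitude of the within-sample expression/GC correlation
  cor_gc <- function(m) {
    lc <- log_cpm(m)
    mean(abs(apply(lc, 2, stats::cor, y = gc, method = "spearman")))
  }
  before <- cor_gc(counts)
  after <- cor_gc(gc_quantile_normalize(counts, gc))
  expect_lt(after, before / 2)
})

test_that("log-CPM matches hand arithmetic and floors zeros at -2", {
  m <- make_counts(matrix(c(0, 15, 3999985), ncol = 1))
  lc <- log_cpm(m)
  expect_equal(lc["g1", 1], -2)
  expect_equal(lc["g2", 1], log2(1e6 * 15 / 4e6 + 0.25))  # CPM 3.75 -> 2
  expect_equal(lc["g2", 1], 2)
  expect_error(log_cpm(make_counts(matrix(0, 2, 1))), "library size")
})

test_that("PCA outlier rule removes planted outliers and spares clouds", {
  set.seed(42)
  removed_frac <- replicate(20, {
    x <- matrix(rnorm(40 * 100), nrow = 40)
    colnames(x) <- paste0("s", 1:100); rownames(x) <- paste0("g", 1:40)
    1 - length(pca_outlier_removal(x, 3)) / 100
  })
  expect_lt(mean(removed_frac), 0.03)           # >= 97 retained on average

  x <- matrix(rnorm(40 * 30), nrow = 40)
  colnames(x) <- paste0("s", 1:30); rownames(x) <- paste0("g", 1:40)
  x[, 7] <- x[, 7] + 10 * sd(x)                 # displaced 10x cloud scale
  expect_false("s7" %in% pca_outlier_removal(x, 3))
  expect_identical(pca_outlier_removal(x, Inf), colnames(x))
  expect_error(pca_outlier_removal(x[, 1:2]), "3 samples")
})

test_that("small batches and duplicates are dropped at the documented
           boundary", {
  md <- data.frame(sample_id = paste0("s", 1:19),
                   batch = rep(c("big", "five", "four"), c(10, 5, 4)))
  kept <- remove_small_batches(md)
  expect_setequal(kept, md$sample_id[md$batch != "four"])  # <=4 dropped, 5 kept
  md2 <- rbind(md, md[1, ])
  expect_equal(sum(remove_small_batches(md2) == "s1"), 1L)
  expect_identical(remove_small_batches(data.frame(sample_id = "a", batch = "x"),
                                        min_batch_size = 1), "a")
  expect_error(remove_small_batches(md[md$batch == "four", ]), "dropped")
})

test_that("ComBat adjustment removes planted batch structure", {
  set.seed(11)
  G <- 150; n <- 50
  batch <- rep(c("A", "B"), each = n)
  base <- matrix(rnorm(G * 2 * n, mean = 5), G,
                 dimnames = list(paste0("g", 1:G), paste0("s", 1:(2 * n))))
  # per-gene planted shifts (sd 2 log2 units) in batch B
  x <- base + outer(rnorm(G, 0, 2), as.numeric(batch == "B"))
  y <- combat_adjust(x, batch)
  diff_means <- abs(rowMeans(y[, batch == "A"]) - rowMeans(y[, batch == "B"]))
  # EB shrinkage leaves small per-gene residuals; removal is near-complete
  # on average
  expect_lt(mean(diff_means), 0.05)
  expect_lt(max(diff_means), 0.3)
  # gene-wise overall means approximately preserved (EB shrinkage keeps the
  # anchor near, not exactly at, the pre-adjustment mean)
  expect_lt(max(abs(rowMeans(y) - rowMeans(x))), 0.01)
  # eta-squared reduced by >= 90%
  e_before <- mean_eta_squared(x, batch)
  e_after <- mean_eta_squared(y, batch)
  expect_lt(e_after, 0.1 * e_before)
  # single batch: identity with warning
  expect_warning(z <- combat_adjust(x, rep("A", 2 * n)), "single batch")
  expect_identical(z, x)
  # zero within-batch variance gene survives with warning
  x2 <- x; x2[1, batch == "A"] <- 3
  expect_warning(y2 <- combat_adjust(x2, batch), "variance")
  expect_identical(y2[1, ], x2[1, ])
})

test_that("small subtypes are excluded but normals always retained", {
  md <- data.frame(
    sample_id = paste0("s", 1:25),
    cancer_type = "T1",
    subtype = c(rep("nine", 9), rep("ten", 10), rep("normal", 6)),
    is_tumor = c(rep(1L, 19), rep(0L, 6)))
  kept <- filter_small_subtypes(md)
  expect_false(any(md$sample_id[md$subtype == "nine"] %in% kept))
  expect_true(all(md$sample_id[md$subtype == "ten"] %in% kept))    # boundary
  expect_true(all(md$sample_id[md$is_tumor == 0L] %in% kept))
  # normals retained even when every subtype is small
  md$subtype[md$subtype == "ten"] <- paste0("t", 1:10)
  kept2 <- filter_small_subtypes(md)
  expect_setequal(kept2, md$sample_id[md$is_tumor == 0L])
})

test_that("preprocessing is equivariant under sample permutation", {
  co <- generate_cohort(small_config(seed = 10))
  md <- co$metadata[co$metadata$cancer_type == "T1", ]
  counts <- co$counts[, md$sample_id]
  p1 <- preprocess_expression(counts, co$gc, md)
  set.seed(1)
  perm <- sample(ncol(counts))
  p2 <- preprocess_expression(counts[, perm], co$gc, md[perm, ])
  shared <- intersect(colnames(p1$expr), colnames(p2$expr))
  expect_setequal(colnames(p1$expr), colnames(p2$expr))
  expect_equal(p1$expr[, shared], p2$expr[, shared], tolerance = 1e-6)
})
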