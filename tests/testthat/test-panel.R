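test_that("Spearman correlation matches hand-computed values", {
  x <- rbind(a = 1:10, b = 10:1, c = c(1, 2, 3, 4, 5, 5, 4, 3, 2, 1))
  y <- 1:10
  res <- spearman_fdr(x, y)
  expect_equal(res$rho[res$variable == "a"], 1)
  expect_equal(res$rho[res$variable == "b"], -1)
  expect_equal(res$q[res$variable == "a"], 0)
  # 5-point example with hand-computed rank covariance: rho = 0.6
  res2 <- spearman_fdr(matrix(c(1, 2, 3, 4, 5), nrow = 1), c(3, 1, 2, 5, 4))
  expect_equal(res2$rho, 0.6)
  # zero-variance variable: rho 0, q 1, warning
  expect_warning(res3 <- spearman_fdr(rbind(k = rep(2, 10), a = 1:10), y),
                 "zero-variance")
  expect_equal(res3$rho[res3$variable == "k"], 0)
  expect_equal(res3$q[res3$variable == "k"], 1)
})

test_that("panel genes lowly expressed in any subtype are flagged", {
  md <- data.frame(sample_id = paste0("s", 1:12),
                   cancer_type = "T1",
                   subtype = rep(c("A", "B", "C"), each = 4),
                   is_tumor = 1L)
  panel <- data.frame(gene_id = c("hi", "low_in_C", "absent"),
                      class = c("MHC", "CAG", "MHC"))
  expr <- rbind(hi = rep(5, 12),
                low_in_C = c(rep(5, 8), rep(-2, 4)))
  colnames(expr) <- md$sample_id
  flagged <- flag_low_expressed_panel(list(T1 = expr), md, panel,
                                      min_median_logcpm = 0)
  expect_setequal(flagged, c("low_in_C", "absent"))
  # gene above threshold everywhere is never flagged
  expect_false("hi" %in% flagged)
})

test_that("immune-correlation filter removes infiltration-tracking genes
           across types and honours the inclusive 0.4 boundary", {
  set.seed(21)
  n <- 60
  imm <- runif(n, 0, 0.6)
  md <- data.frame(sample_id = paste0("s", 1:n), cancer_type = "T1",
                   subtype = "A", is_tumor = 1L)
  # tracks immune fraction almost perfectly; independent; noisy tracker
  expr <- rbind(tracker = 2 * imm + rnorm(n, sd = 0.01),
                indep = rnorm(n))
  colnames(expr) <- md$sample_id
  panel <- data.frame(gene_id = c("tracker", "indep"),
                      class = c("CAG", "CAG"))
  names(imm) <- md$sample_id
  out <- immune_correlation_filter(list(T1 = expr), imm, md, panel)
  expect_setequal(out$removed, "tracker")
  expect_setequal(out$panel$gene_id, "indep")

  # rho just under threshold survives even when significant: construct a
  # variable with sample rho in (0.35, 0.4)
  found <- FALSE
  for (s in 1:50) {
    set.seed(100 + s)
    g <- 0.4 * scale(imm)[, 1] + rnorm(n)
    r <- cor(rank(g), rank(imm))
    if (r > 0.35 && r < 0.3999) { found <- TRUE; break }
  }
  expect_true(found)
  expr2 <- rbind(border = g, tracker = 2 * imm + rnorm(n, sd = 0.01))
  colnames(expr2) <- md$sample_id
  panel2 <- data.frame(gene_id = c("border", "tracker"), class = "CAG")
  out2 <- immune_correlation_filter(list(T1 = expr2), imm, md, panel2)
  expect_true("border" %in% out2$panel$gene_id)
  # absolute mode also catches strong negative correlation
  expr3 <- rbind(anti = -2 * imm + rnorm(n, sd = 0.01))
  colnames(expr3) <- md$sample_id
  panel3 <- data.frame(gene_id = "anti", class = "CAG")
  expect_equal(nrow(immune_correlation_filter(list(T1 = expr3), imm, md,
                                              panel3)$panel), 1L)
  expect_equal(nrow(immune_correlation_filter(list(T1 = expr3), imm, md,
                                              panel3,
                                              mode = "absolute")$panel), 0L)
})

test_that("null cohorts pass the filter nearly untouched", {
  # no immune-driven genes: false-removal rate stays near zero
  removed <- integer(20)
  total <- integer(20)
  for (s in 1:20) {
    set.seed(300 + s)
    n <- 50
    imm <- runif(n, 0, 0.6); names(imm) <- paste0("s", 1:n)
    md <- data.frame(sample_id = names(imm), cancer_type = "T1",
                     subtype = "A", is_tumor = 1L)
    expr <- matrix(rnorm(40 * n), 40,
                   dimnames = list(paste0("g", 1:40), names(imm)))
    panel <- data.frame(gene_id = rownames(expr), class = "CAG")
    out <- immune_correlation_filter(list(T1 = expr), imm, md, panel)
    removed[s] <- length(out$removed); total[s] <- 40
  }
  expect_lte(sum(removed) / sum(total), 0.05 + 0.03)
})

test_that("planted immune-driven genes are excluded and clean genes kept
           across replicate cohorts", {
  # aggregate over replicate cohorts; driven MHC genes additionally carry
  # archetype shifts that partially mask their immune correlation, so the
  # near-complete exclusion guarantee applies to genes without planted
  # subtype structure
  excl_clean <- c(); excl_all <- c(); kept_null <- c()
  for (s in 1:3) {
    co <- generate_cohort(cohort_config(seed = 600 + s))
    md <- co$metadata
    expr_by_type <- lapply(unique(md$cancer_type), function(ct) {
      sel <- md$sample_id[md$cancer_type == ct]
      preprocess_expression(co$counts[, sel], co$gc,
                            md[md$sample_id %in% sel, ])$expr
    })
    names(expr_by_type) <- unique(md$cancer_type)
    fr <- suppressWarnings(rpc_deconvolve(co$betas, co$reference))
    low <- flag_low_expressed_panel(expr_by_type, md, co$panel, 0)
    pe <- co$panel[!co$panel$gene_id %in% low, , drop = FALSE]
    filt <- immune_correlation_filter(expr_by_type, fr[, "immune"], md, pe)
    driven <- intersect(names(co$truth$immune_driven)[co$truth$immune_driven],
                        co$panel$gene_id)
    mhc_driven <- intersect(driven, co$panel$gene_id[co$panel$class == "MHC"])
    clean_driven <- setdiff(driven, mhc_driven)
    null_in <- setdiff(pe$gene_id, driven)
    excl_clean <- c(excl_clean,
                    !clean_driven %in% filt$panel$gene_id)
    excl_all <- c(excl_all, !driven %in% filt$panel$gene_id)
    kept_null <- c(kept_null, null_in %in% filt$panel$gene_id)
    # determinism: the retained panel is a function of the cohort
    filt2 <- immune_correlation_filter(rev(expr_by_type), fr[, "immune"],
                                       md, pe)
    expect_setequal(filt$panel$gene_id, filt2$panel$gene_id)
  }
  expect_gte(mean(excl_clean), 0.95)
  expect_gte(mean(excl_all), 0.90)
  expect_gte(mean(kept_null), 0.90)
})

test_that("the signed pan-cancer summary counts strong correlations", {
  set.seed(31)
  n <- 40
  mk <- function() {
    base <- rnorm(n)
    m <- rbind(v1 = base, v2 = base,                  # identical pair
               v3 = rnorm(n), v4 = rnorm(n))          # independent pair
    colnames(m) <- paste0("s", 1:n)
    m
  }
  types <- replicate(13, mk(), simplify = FALSE)
  names(types) <- paste0("T", 1:13)
  cs <- pan_cancer_correlation_summary(types)
  expect_equal(cs$summary["v1", "v2"], 13L)
  expect_true(is.na(cs$summary["v1", "v1"]))
  expect_true(abs(cs$summary["v3", "v4"]) <= 1)
  expect_true(isSymmetric(unname(ifelse(is.na(cs$summary), 0L, cs$summary))))

  # one type with a strong negative pair, others null -> entry -1
  types2 <- lapply(1:5, function(i) {
    set.seed(400 + i)
    m <- rbind(a = rnorm(n), b = rnorm(n))
    colnames(m) <- paste0("s", 1:n)
    if (i == 1) m["b", ] <- -0.95 * m["a", ] + rnorm(n, sd = 0.1)
    m
  })
  names(types2) <- paste0("T", 1:5)
  cs2 <- pan_cancer_correlation_summary(types2)
  expect_equal(cs2$summary["a", "b"], -1L)

  # a variable missing in some type contributes 0 there
  types3 <- types2
  types3$T1 <- types3$T1["a", , drop = FALSE]
  cs3 <- pan_cancer_correlation_summary(types3)
  expect_equal(cs3$summary["a", "b"], 0L)
  expect_error(pan_cancer_correlation_summary(types3["T1"]), ">= 2 cancer")
})
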