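#' Run the three clustering algorithms over a range of K
#'
#' Hierarchical clustering (Ward linkage on Euclidean distance, tree cut at
#' K), k-means (25 restarts, seeded) and PAM (build + swap on Euclidean
#' distance), each for every K in `K_range`.
#'
#' @param m rows-by-features numeric matrix (e.g. subtypes by MHC-gene
#'   probabilities). Rows with missing values are dropped with a warning.
#' @param K_range candidate cluster numbers; default 2:5.
#' @param seed seed for the k-means restarts.
#' @return list with `assignments[[algorithm]][[as.character(K)]]` (named
#'   integer vectors) and `matrix` (the rows actually clustered).
#' @export
run_algorithms <- function(m, K_range = 2:5, seed = 1L) {
  if (anyNA(m)) {
    drop <- apply(m, 1, anyNA)
    warnf("dropping %d row(s) with missing values", sum(drop))
    m <- m[!drop, , drop = FALSE]
  }
  if (nrow(m) < max(K_range) + 1) stopf("need more rows than max(K_range)")
  if (any(K_range < 2) || any(K_range > nrow(m) - 1)) {
    stopf("K_range must lie within 2..(rows-1)")
  }
  d <- stats::dist(m)
  hc <- stats::hclust(d, method = "ward.D2")
  assignments <- list(hierarchical = list(), kmeans = list(), pam = list())
  for (K in K_range) {
    kk <- as.character(K)
    assignments$hierarchical[[kk]] <- stats::cutree(hc, k = K)
    set.seed(derive_seed(seed, K))
    assignments$kmeans[[kk]] <- stats::setNames(
      stats::kmeans(m, centers = K, nstart = 25)$cluster, rownames(m))
    assignments$pam[[kk]] <- stats::setNames(
      cluster::pam(d, k = K, cluster.only = TRUE), rownames(m))
  }
  list(assignments = assignments, matrix = m, K_range = K_range)
}

#' Orientations of the validity-index battery
#'
#' @return named character vector, `"max"` (higher is better) or `"min"`.
#' @export
validity_orientations <- function() {
  c(silhouette = "max", calinski_harabasz = "max", davies_bouldin = "min",
    dunn = "max", connectivity = "min", c_index = "min", wss = "min",
    bw_ratio = "max", gap = "max", pbm = "max", xie_beni = "min",
    separation_gap = "max")
}

#' Internal cluster validity indices for one partition
#'
#' Computes a fixed battery of 12 indices: average silhouette width,
#' Calinski-Harabasz, Davies-Bouldin, Dunn, connectivity (10 nearest
#' neighbours), C-index, within-cluster sum of squares, between/within
#' variance ratio, gap statistic (20 uniform-reference draws over the
#' bounding box, clustering each draw with k-means at the same K), PBM,
#' Xie-Beni, and the separation gap (mean between-cluster minus mean
#' within-cluster distance). Indices undefined for a partition (e.g. with
#' singleton clusters) are returned as `NA` and treated as worst-rank during
#' aggregation.
#'
#' @param m rows-by-features matrix.
#' @param assignment integer cluster labels for the rows.
#' @param n_neighbors neighbourhood size for connectivity; default 10.
#' @param gap_b number of uniform reference draws for the gap statistic.
#' @param gap_seed seed for the reference draws.
#' @return named numeric vector over the battery of
#'   [validity_orientations()].
#' @export
validity_indices <- function(m, assignment, n_neighbors = 10L, gap_b = 20L,
                             gap_seed = 1L) {
  cl <- as.integer(factor(assignment))
  k <- length(unique(cl))
  n <- nrow(m)
  if (k < 2) stopf("need >= 2 clusters")
  D <- as.matrix(stats::dist(m))
  if (max(D) == 0) stopf("all points identical: validity indices undefined")
  idx <- stats::setNames(rep(NA_real_, length(validity_orientations())),
                         names(validity_orientations()))
  try_na <- function(expr) tryCatch(expr, error = function(e) NA_real_)

  centroids <- vapply(seq_len(k), function(j)
    colMeans(m[cl == j, , drop = FALSE]), numeric(ncol(m)))
  centroids <- t(matrix(centroids, nrow = ncol(m)))   # k x features
  grand <- colMeans(m)
  sizes <- as.integer(table(cl))
  within_ss_per <- vapply(seq_len(k), function(j) {
    sum(sweep(m[cl == j, , drop = FALSE], 2, centroids[j, ])^2)
  }, numeric(1))
  wss <- sum(within_ss_per)
  bss <- sum(sizes * rowSums(sweep(centroids, 2, grand)^2))

  same <- outer(cl, cl, "==")
  ut <- upper.tri(D)
  dw <- D[same & ut]; db <- D[!same & ut]

  idx["silhouette"] <- try_na(
    if (min(sizes) < 1) NA_real_ else
      mean(cluster::silhouette(cl, stats::dist(m))[, "sil_width"]))
  idx["calinski_harabasz"] <- try_na(
    if (n - k == 0) NA_real_ else (bss / (k - 1)) / (wss / (n - k)))
  idx["davies_bouldin"] <- try_na({
    s <- vapply(seq_len(k), function(j)
      mean(sqrt(rowSums(sweep(m[cl == j, , drop = FALSE], 2,
                              centroids[j, ])^2))), numeric(1))
    cd <- as.matrix(stats::dist(centroids))
    if (any(cd[upper.tri(cd)] == 0)) NA_real_ else
      mean(vapply(seq_len(k), function(i)
        max(vapply(setdiff(seq_len(k), i), function(j)
          (s[i] + s[j]) / cd[i, j], numeric(1))), numeric(1)))
  })
  idx["dunn"] <- try_na(if (max(dw) == 0) NA_real_ else min(db) / max(dw))
  idx["connectivity"] <- try_na({
    L <- min(n_neighbors, n - 1)
    conn <- 0
    for (i in seq_len(n)) {
      nn <- order(D[i, -i])
      others <- seq_len(n)[-i]
      disagree <- cl[others[nn[seq_len(L)]]] != cl[i]
      conn <- conn + sum(disagree / seq_len(L))
    }
    conn
  })
  idx["c_index"] <- try_na({
    nw <- length(dw)
    ds <- sort(D[ut])
    smin <- sum(ds[seq_len(nw)])
    smax <- sum(ds[seq.int(length(ds) - nw + 1, length(ds))])
    if (smax == smin) NA_real_ else (sum(dw) - smin) / (smax - smin)
  })
  idx["wss"] <- wss
  idx["bw_ratio"] <- try_na(if (wss == 0) NA_real_ else bss / wss)
  idx["gap"] <- try_na({
    set.seed(gap_seed)
    lo <- apply(m, 2, min); hi <- apply(m, 2, max)
    ref <- vapply(seq_len(gap_b), function(b) {
      mb <- matrix(stats::runif(n * ncol(m), rep(lo, each = n),
                                rep(hi, each = n)), nrow = n)
      km <- stats::kmeans(mb, centers = k, nstart = 5)
      log(sum(km$withinss) + .Machine$double.eps)
    }, numeric(1))
    mean(ref) - log(wss + .Machine$double.eps)
  })
  idx["pbm"] <- try_na({
    e1 <- sum(sqrt(rowSums(sweep(m, 2, grand)^2)))
    ek <- sum(vapply(seq_len(k), function(j)
      sum(sqrt(rowSums(sweep(m[cl == j, , drop = FALSE], 2,
                             centroids[j, ])^2))), numeric(1)))
    dk <- max(stats::dist(centroids))
    if (ek == 0) NA_real_ else ((1 / k) * (e1 / ek) * dk)^2
  })
  idx["xie_beni"] <- try_na({
    mind <- min(stats::dist(centroids))
    if (mind == 0) NA_real_ else wss / (n * mind^2)
  })
  idx["separation_gap"] <- try_na(mean(db) - mean(dw))
  idx
}

#' Build the full validity table over algorithms and K
#'
#' @param run output of [run_algorithms()].
#' @param gap_seed seed for the gap-statistic reference draws.
#' @return data.frame with columns `algorithm`, `K`, `index`, `score`,
#'   `orientation`.
#' @export
validity_table <- function(run, gap_seed = 1L) {
  ori <- validity_orientations()
  rows <- list()
  for (alg in names(run$assignments)) {
    for (kk in names(run$assignments[[alg]])) {
      scores <- validity_indices(run$matrix, run$assignments[[alg]][[kk]],
                                 gap_seed = derive_seed(gap_seed, paste(alg, kk)))
      rows[[paste(alg, kk)]] <- data.frame(
        algorithm = alg, K = as.integer(kk), index = names(scores),
        score = unname(scores), orientation = unname(ori[names(scores)]),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Select the optimal K by validity-index rank aggregation
#'
#' For every (algorithm, index) pair the candidate K are ranked best-to-worst
#' respecting the index orientation (`NA` scores get the worst rank); the
#' selected K minimizes the mean rank over all pairs, ties broken toward
#' smaller K.
#'
#' @param validity data.frame from [validity_table()].
#' @return list with `selected_K` and `mean_ranks` (named by K).
#' @export
aggregate_optimal_k <- function(validity) {
  Ks <- sort(unique(validity$K))
  if (length(Ks) < 2) stopf("need >= 2 candidate K")
  rank_rows <- list()
  for (alg in unique(validity$algorithm)) {
    for (ix in unique(validity$index)) {
      sel <- validity$algorithm == alg & validity$index == ix
      sub <- validity[sel, , drop = FALSE]
      sub <- sub[match(Ks, sub$K), , drop = FALSE]
      sc <- sub$score
      if (all(is.na(sc))) next
      if (sub$orientation[which(!is.na(sub$orientation))[1]] == "max") sc <- -sc
      sc[is.na(sc)] <- Inf                      # undefined -> worst
      rank_rows[[paste(alg, ix)]] <- rank(sc, ties.method = "average")
    }
  }
  rk <- do.call(rbind, rank_rows)
  mean_ranks <- stats::setNames(colMeans(rk), Ks)
  selected <- Ks[which(mean_ranks == min(mean_ranks))[1]]  # ties -> smaller K
  list(selected_K = selected, mean_ranks = mean_ranks)
}

## best label permutation of `from` onto `to` by maximum agreement
align_labels <- function(from, to, K) {
  A <- matrix(0L, K, K)
  for (i in seq_len(K)) for (j in seq_len(K)) {
    A[i, j] <- sum(from == i & to == j)
  }
  perm <- as.integer(clue::solve_LSAP(A, maximum = TRUE))
  stats::setNames(perm[from], names(from))
}

#' Consensus assignment across the three algorithms
#'
#' PAM and hierarchical labels are aligned to the k-means labels by
#' maximum-agreement bipartite matching (Hungarian algorithm); consensus is
#' the per-row majority vote. Rows where all three algorithms disagree are
#' assigned to the cluster whose centroid (mean of the unanimously assigned
#' members) is nearest in Euclidean distance. Algorithms yielding fewer than
#' K non-empty clusters are excluded from the vote with a message.
#'
#' @param run output of [run_algorithms()].
#' @param K the selected number of clusters.
#' @return named integer vector of consensus labels (k-means label space).
#' @export
consensus_assignments <- function(run, K) {
  kk <- as.character(K)
  votes <- list()
  base <- run$assignments$kmeans[[kk]]
  if (is.null(base)) stopf("no assignments at K = %d", K)
  for (alg in names(run$assignments)) {
    a <- run$assignments[[alg]][[kk]]
    if (length(unique(a)) < K) {
      message(sprintf("algorithm %s produced < %d clusters; excluded", alg, K))
      next
    }
    votes[[alg]] <- if (alg == "kmeans") a else align_labels(a, base, K)
  }
  V <- do.call(cbind, votes)
  consensus <- apply(V, 1, function(v) {
    tb <- table(v)
    if (max(tb) > 1 || length(tb) == 1) as.integer(names(tb)[which.max(tb)])
    else NA_integer_
  })
  if (anyNA(consensus)) {
    unanimous <- apply(V, 1, function(v) length(unique(v)) == 1)
    m <- run$matrix
    cent <- vapply(seq_len(K), function(j) {
      members <- which(unanimous & consensus == j)
      if (length(members) == 0) members <- which(consensus == j)
      colMeans(m[members, , drop = FALSE])
    }, numeric(ncol(m)))
    for (i in which(is.na(consensus))) {
      dd <- vapply(seq_len(K), function(j) sum((m[i, ] - cent[, j])^2),
                   numeric(1))
      consensus[i] <- which.min(dd)
    }
  }
  stats::setNames(as.integer(consensus), rownames(run$matrix))
}

#' Label clusters MHC-low / MHC-intermediate / MHC-high
#'
#' Clusters are ordered by their mean MHC probability (mean over member
#' subtypes and all MHC columns): at K = 3 the lowest is `MHC-low`, the
#' middle `MHC-intermediate`, the highest `MHC-high`; at other K clusters
#' are labeled `cluster_1..cluster_K` by ascending mean. Ties in means are
#' broken by cluster size (larger cluster ranked lower), with a message.
#'
#' @param consensus named integer consensus labels.
#' @param m the clustered subtype-by-MHC-probability matrix.
#' @return list of class `"mhc_clustering"`: `selected_K`, `consensus`,
#'   `class_of_cluster` (cluster id -> label), `subtype_class` (named by
#'   subtype), `cluster_means`.
#' @export
label_mhc_clusters <- function(consensus, m) {
  K <- length(unique(consensus))
  if (K < 2) stopf("need >= 2 clusters to label")
  means <- vapply(sort(unique(consensus)), function(j)
    mean(m[consensus == j, , drop = FALSE]), numeric(1))
  sizes <- as.integer(table(consensus)[as.character(sort(unique(consensus)))])
  if (anyDuplicated(means)) {
    message("tie in cluster means broken by cluster size (larger = lower)")
  }
  ord <- order(means, -sizes)
  labels <- if (K == 3) c("MHC-low", "MHC-intermediate", "MHC-high")
            else sprintf("cluster_%d", seq_len(K))
  class_of <- stats::setNames(labels, sort(unique(consensus))[ord])
  subtype_class <- stats::setNames(class_of[as.character(consensus)],
                                   names(consensus))
  structure(list(selected_K = K, consensus = consensus,
                 class_of_cluster = class_of, subtype_class = subtype_class,
                 cluster_means = stats::setNames(means[ord], labels)),
            class = "mhc_clustering")
}

#' Cluster the subtype MHC-probability matrix end to end
#'
#' Runs the three algorithms over `K_range`, builds the validity table,
#' selects K by rank aggregation, forms the consensus assignment and labels
#' the clusters by mean MHC probability.
#'
#' @param m subtype-by-MHC-gene relative-effect matrix.
#' @param K_range candidate K; default 2:5.
#' @param seed seed for k-means restarts and gap references.
#' @return list with the `"mhc_clustering"` result plus `validity`,
#'   `run`, and `heatmap_matrix` (rows ordered by cluster then mean
#'   probability, plot-ready).
#' @export
cluster_mhc <- function(m, K_range = 2:5, seed = 1L) {
  run <- run_algorithms(m, K_range = K_range, seed = seed)
  validity <- validity_table(run, gap_seed = derive_seed(seed, "gap"))
  agg <- aggregate_optimal_k(validity)
  consensus <- consensus_assignments(run, agg$selected_K)
  labeled <- label_mhc_clusters(consensus, run$matrix)
  row_means <- rowMeans(run$matrix)
  cls <- labeled$subtype_class
  ord <- order(match(cls, names(labeled$cluster_means)), row_means)
  list(result = labeled, validity = validity, mean_ranks = agg$mean_ranks,
       run = run, heatmap_matrix = run$matrix[ord, , drop = FALSE])
}
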