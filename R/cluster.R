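#' Latent semantic indexing embedding
#'
#' TF-IDF weighting (applied internally when the input is raw) followed by a
#' truncated SVD. Components whose absolute correlation with log total
#' counts exceeds `depth_cor_max` are flagged as depth components and can be
#' dropped; the first LSI component usually tracks sequencing depth in
#' sparse chromatin data.
#'
#' @param m a [modality_matrix()] or sparse cells x features matrix.
#' @param d number of components requested.
#' @param drop_depth drop flagged components from the coordinates.
#' @param depth_cor_max absolute-correlation threshold for flagging.
#' @return an `Embedding`: `coords` (cells x kept components), `singular_values`,
#'   `depth_correlation`, `depth_flag`, factor matrix `u`, and `method = "lsi"`.
#' @export
lsi <- function(m, d = 20, drop_depth = FALSE, depth_cor_max = 0.75) {
  raw <- if (inherits(m, "ModalityMatrix")) m$counts else m
  cells <- rownames(raw)
  depth <- Matrix::rowSums(raw)
  w <- if (isTRUE(attr(m, "tfidf"))) raw else tfidf(raw)
  x <- as.matrix(w)
  d_max <- min(dim(x)) - 1L
  if (d > d_max) {
    warnf("d = %d exceeds matrix rank bound; returning %d components", d, d_max)
    d <- d_max
  }
  # cells << features here, so eigendecompose the cell-cell Gram matrix
  gram <- tcrossprod(x)
  eig <- eigen(gram, symmetric = TRUE)
  keep <- seq_len(d)
  sv <- sqrt(pmax(eig$values[keep], 0))
  u <- eig$vectors[, keep, drop = FALSE]
  coords <- u %*% diag(sv, d, d)
  logd <- log1p(depth)
  dc <- suppressWarnings(apply(coords, 2, function(v) {
    if (sd(v) == 0 || sd(logd) == 0) 0 else cor(v, logd)
  }))
  flag <- abs(dc) > depth_cor_max
  if (drop_depth && any(flag) && !all(flag)) {
    coords <- coords[, !flag, drop = FALSE]
    u_kept <- u[, !flag, drop = FALSE]
    sv_kept <- sv[!flag]
  } else {
    u_kept <- u
    sv_kept <- sv
  }
  rownames(coords) <- cells
  structure(list(coords = coords, singular_values = sv_kept, u = u_kept,
                 all_singular_values = sv, depth_correlation = dc,
                 depth_flag = flag, method = "lsi"), class = "Embedding")
}

knn_indices <- function(coords, k) {
  n <- nrow(coords)
  k <- min(k, n - 1)
  dm <- as.matrix(dist(coords))
  t(apply(dm, 1, function(row) order(row)[2:(k + 1)]))  # excl. self
}

#' Shared-nearest-neighbor graph clustering
#'
#' Builds a k-nearest-neighbor graph in the embedding, weights edges by the
#' Jaccard overlap of neighborhoods (shared / (2k - shared)), prunes weak
#' edges and optimizes modularity with the multilevel (Louvain) greedy
#' algorithm. Deterministic given `seed`.
#'
#' @param embedding an [lsi()] `Embedding` or a coordinate matrix.
#' @param k_neighbors neighbors per cell.
#' @param resolution modularity resolution.
#' @param prune minimum Jaccard weight kept.
#' @param seed integer seed.
#' @return integer cluster labels (1-based), named by cell when available.
#' @export
snn_cluster <- function(embedding, k_neighbors = 20, resolution = 1.0,
                        prune = 1 / 15, seed = 1L) {
  coords <- if (inherits(embedding, "Embedding")) embedding$coords else embedding
  n <- nrow(coords)
  k <- min(k_neighbors, n - 1)
  nn <- knn_indices(coords, k)
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), k), j = as.vector(nn), x = 1,
                            dims = c(n, n))
  shared <- Matrix::tcrossprod(A)
  trip <- Matrix::summary(shared)
  w <- trip$x / (2 * k - trip$x)
  keep <- trip$i < trip$j & w >= prune
  g <- igraph::graph_from_data_frame(
    data.frame(from = trip$i[keep], to = trip$j[keep], weight = w[keep]),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  cl <- with_seed(seed, igraph::cluster_louvain(g, resolution = resolution))
  labels <- integer(n)
  labels[as.integer(igraph::V(g)$name)] <- igraph::membership(cl)
  names(labels) <- rownames(coords)
  labels
}

#' Wilcoxon rank-sum test
#'
#' Two-sided rank-sum test with an explicit small-sample policy: when
#' `min(|x|, |y|) <= 8` and there are no ties, the exact null distribution
#' of U is used; otherwise the normal approximation with tie correction and
#' continuity correction.
#'
#' @param x,y numeric vectors (both non-empty).
#' @return list with `U` (statistic for `x`), `p` (two-sided), and `exact`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (!n1 || !n2) stopf("both groups must be non-empty")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (min(n1, n2) <= 8 && !ties) {
    p <- min(1, 2 * min(pwilcox(U, n1, n2), pwilcox(U - 1, n1, n2, lower.tail = FALSE)))
    return(list(U = U, p = p, exact = TRUE))
  }
  N <- n1 + n2
  tie_tab <- table(r)
  tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * (N + 1 - tie_term)
  mu <- n1 * n2 / 2
  if (sigma2 <= 0) return(list(U = U, p = 1, exact = FALSE))
  z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
  p <- min(1, 2 * pnorm(-max(z, 0)))
  list(U = U, p = p, exact = FALSE)
}

# Vectorised one-vs-rest rank-sum p-values for all columns of a dense matrix.
# Ranks are computed once per feature over all cells; normal approximation
# with tie and continuity correction (groups here are far above the exact-
# policy cutoff; tiny groups fall back to wilcoxon_rank_sum()).
ranksum_all_features <- function(X, in_group) {
  n1 <- sum(in_group); n2 <- sum(!in_group); N <- n1 + n2
  R <- apply(X, 2, rank)
  rsum <- colSums(R[in_group, , drop = FALSE])
  U <- rsum - n1 * (n1 + 1) / 2
  tie_term <- apply(R, 2, function(r) {
    tt <- table(r)
    sum(tt^3 - tt)
  }) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * (N + 1 - tie_term)
  mu <- n1 * n2 / 2
  z <- (abs(U - mu) - 0.5) / sqrt(pmax(sigma2, .Machine$double.eps))
  p <- pmin(1, 2 * pnorm(-pmax(z, 0)))
  p[sigma2 <= 0] <- 1
  list(U = U, p = p)
}

#' Rank cluster marker features by one-vs-rest Wilcoxon tests
#'
#' Per cluster, each feature is tested cluster-vs-rest with the rank-sum
#' test; features with `p < p_max` (raw by default, matching common marker
#' practice; set `fdr = TRUE` for BH-adjusted filtering) and
#' `logFC > min_logfc` are kept, ranked by p then logFC, and the top
#' `top_n` returned. `logFC` is the log2 ratio of mean depth-normalized
#' signal with pseudocount 1; `capture_rate` is the fraction of cluster
#' cells with a nonzero count at the feature.
#'
#' @param m a [modality_matrix()] (raw counts).
#' @param labels cluster labels, one per cell.
#' @param p_max,min_logfc,top_n filter and ranking parameters.
#' @param fdr filter on BH-adjusted p instead of raw p.
#' @param min_cluster_size clusters smaller than this are skipped (warning).
#' @return `MarkerStat` data.frame: feature, cluster, p, logFC, capture_rate,
#'   rank.
#' @export
rank_markers <- function(m, labels, p_max = 0.05, min_logfc = 0, top_n = 200,
                         fdr = FALSE, min_cluster_size = 3) {
  if (length(unique(labels)) < 2)
    stopf("need at least two clusters for one-vs-rest tests")
  X <- as.matrix(m$counts)
  depth <- pmax(rowSums(X), 1)
  Xn <- X / depth * 1e4
  out <- list()
  for (cl in sort(unique(labels))) {
    idx <- labels == cl
    if (sum(idx) < min_cluster_size) {
      warnf("cluster %s has fewer than %d cells; skipped", cl, min_cluster_size)
      next
    }
    if (min(sum(idx), sum(!idx)) <= 8) {
      stats_cl <- lapply(seq_len(ncol(X)), function(j)
        wilcoxon_rank_sum(X[idx, j], X[!idx, j]))
      p <- vapply(stats_cl, `[[`, numeric(1), "p")
    } else {
      p <- ranksum_all_features(X, idx)$p
    }
    m1 <- colMeans(Xn[idx, , drop = FALSE])
    m0 <- colMeans(Xn[!idx, , drop = FALSE])
    logfc <- log2((m1 + 1) / (m0 + 1))
    cap <- colMeans(X[idx, , drop = FALSE] > 0)
    pf <- if (fdr) p.adjust(p, "BH") else p
    keep <- which(pf < p_max & logfc > min_logfc)
    if (!length(keep)) next
    ord <- keep[order(p[keep], -logfc[keep])]
    ord <- head(ord, top_n)
    out[[as.character(cl)]] <- data.frame(
      feature = m$features$feature_id[ord], feature_index = ord,
      cluster = cl, p = p[ord], logFC = logfc[ord], capture_rate = cap[ord],
      rank = seq_along(ord), stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(feature = character(), feature_index = integer(),
               cluster = labels[0], p = numeric(), logFC = numeric(),
               capture_rate = numeric(), rank = integer())
  rownames(res) <- NULL
  res
}

#' Pseudobulk PCA over top marker regions
#'
#' Per cluster and modality, cells are summed to a pseudobulk profile; the
#' `top_k` markers of every cluster across all modalities are pooled,
#' overlapping regions merged, pseudobulk counts re-aggregated over the
#' merged regions, depth-normalized (counts per 10k, log1p) and decomposed
#' by PCA. Profiles from the same cell population cluster together
#' regardless of modality of origin.
#'
#' @param matrices named list of [modality_matrix()] objects sharing cells.
#' @param labels cluster labels shared across modalities.
#' @param top_k markers per cluster and modality.
#' @param marker_args extra arguments to [rank_markers()].
#' @return list with `scores` (profiles x PC), `sdev`, `rotation`, `regions`
#'   (merged marker regions) and `profiles` (cluster/modality key).
#' @export
pseudobulk_pca <- function(matrices, labels, top_k = 50, marker_args = list()) {
  marker_sets <- lapply(matrices, function(m)
    do.call(rank_markers, c(list(m = m, labels = labels, top_n = top_k),
                            marker_args)))
  reg <- do.call(rbind, lapply(seq_along(matrices), function(i) {
    ms <- marker_sets[[i]]
    if (!nrow(ms)) return(NULL)
    matrices[[i]]$features[ms$feature_index, c("chrom", "start", "end")]
  }))
  if (is.null(reg) || !nrow(reg)) stopf("no marker regions found")
  merged <- GenomicRanges::reduce(GenomicRanges::sort(df_to_granges(reg)))
  prof <- list(); key <- list()
  for (mn in names(matrices)) {
    m <- matrices[[mn]]
    fgr <- df_to_granges(m$features)
    ov <- GenomicRanges::findOverlaps(fgr, merged)
    # feature -> merged-region aggregation matrix
    agg <- Matrix::sparseMatrix(i = S4Vectors::queryHits(ov),
                                j = S4Vectors::subjectHits(ov), x = 1,
                                dims = c(ncol(m$counts), length(merged)))
    for (cl in sort(unique(labels))) {
      pb <- Matrix::colSums(m$counts[labels == cl, , drop = FALSE])
      v <- as.numeric(pb %*% agg)
      prof[[length(prof) + 1]] <- log1p(v / max(sum(v), 1) * 1e4)
      key[[length(key) + 1]] <- data.frame(modality = mn, cluster = cl,
                                           stringsAsFactors = FALSE)
    }
  }
  Xp <- do.call(rbind, prof)
  keys <- do.call(rbind, key)
  pc <- prcomp(Xp, center = TRUE, scale. = FALSE)
  rownames(pc$x) <- paste(keys$modality, keys$cluster, sep = "|")
  list(scores = pc$x, sdev = pc$sdev, rotation = pc$rotation,
       regions = merged, profiles = keys)
}
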