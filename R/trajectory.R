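#' Pseudotime along a cluster-centroid principal path
#'
#' Approximates a principal-curve trajectory for a single unbranched
#' lineage: a minimum-spanning tree is built over cluster centroids in the
#' embedding, the path runs from `start_cluster` to the farthest leaf (by
#' path length), cells are orthogonally projected onto the piecewise-linear
#' path, and arc length is rescaled to [0, 1].
#'
#' @param embedding an [lsi()] `Embedding` or coordinate matrix.
#' @param labels cluster labels per cell.
#' @param start_cluster label of the root cluster.
#' @return a `TrajectoryResult`: `t` (per-cell pseudotime), `path` (ordered
#'   cluster labels), `projection_distance` (per-cell distance to the path).
#' @export
fit_pseudotime <- function(embedding, labels, start_cluster) {
  coords <- if (inherits(embedding, "Embedding")) embedding$coords else embedding
  labels <- as.character(labels)
  cls <- sort(unique(labels))
  if (!as.character(start_cluster) %in% cls) stopf("start_cluster '%s' absent",
                                                   start_cluster)
  cent <- do.call(rbind, lapply(cls, function(cl)
    colMeans(coords[labels == cl, , drop = FALSE])))
  rownames(cent) <- cls
  if (length(cls) == 1) {
    # degenerate: single cluster, order along first embedding axis
    t <- coords[, 1] - min(coords[, 1])
    t <- if (max(t) > 0) t / max(t) else t
    return(structure(list(t = t, path = cls,
                          projection_distance = rep(0, nrow(coords))),
                     class = "TrajectoryResult"))
  }
  dm <- as.matrix(dist(cent))
  g <- igraph::graph_from_adjacency_matrix(dm, mode = "undirected", weighted = TRUE)
  mst <- igraph::mst(g)
  root <- as.character(start_cluster)
  dists <- igraph::distances(mst, v = root)
  leaf <- colnames(dists)[which.max(dists[1, ])]
  path_v <- igraph::shortest_paths(mst, from = root, to = leaf)$vpath[[1]]
  path <- igraph::V(mst)$name[as.integer(path_v)]
  P <- cent[path, , drop = FALSE]
  seg_vec <- diff(P)
  seg_len <- sqrt(rowSums(seg_vec^2))
  cum <- c(0, cumsum(seg_len))
  total <- cum[length(cum)]
  n <- nrow(coords)
  n_seg <- nrow(seg_vec)
  best_arc <- numeric(n); best_d2 <- rep(Inf, n)
  for (s in seq_len(n_seg)) {
    a <- P[s, ]; v <- seg_vec[s, ]; L2 <- sum(v^2)
    diffm <- sweep(coords, 2, a)
    u <- if (L2 > 0) as.numeric(diffm %*% v) / L2 else rep(0, n)
    # terminal segments extend (by at most one segment length) beyond the
    # centroids so end cells are ordered rather than piled onto the path
    # tips, without letting off-path outliers stretch the scale
    lo <- if (s == 1) -1 else 0
    hi <- if (s == n_seg) 2 else 1
    u <- pmin(pmax(u, lo), hi)
    proj <- outer(u, v)
    d2 <- rowSums((diffm - proj)^2)
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_arc[upd] <- cum[s] + u[upd] * seg_len[s]
  }
  rng <- range(best_arc)
  t <- if (diff(rng) > 0) (best_arc - rng[1]) / diff(rng) else best_arc * 0
  names(t) <- rownames(coords)
  structure(list(t = t, path = path, projection_distance = sqrt(best_d2)),
            class = "TrajectoryResult")
}

#' Meta-region score: summed normalized signal over a region set
#'
#' Per region, counts are depth-normalized per cell (count / cell total x
#' median cell total) and then scaled to [0, 1] by the region's maximum
#' across cells; the score is the sum over regions. Tracks a chromatin
#' program (e.g. the top opening regions) along pseudotime.
#'
#' @param m a [modality_matrix()] (raw counts).
#' @param features feature ids or column indices of the selected regions.
#' @param cell_depth per-cell totals used for depth normalization; defaults
#'   to the matrix row sums. Pass the cell's total fragment count when `m`
#'   holds only the selected regions, otherwise the normalization divides
#'   out the very signal being scored.
#' @return a `MetaRegionScore` numeric vector (one score per cell) with the
#'   normalized region matrix in `attr(, "region_matrix")` (cells x regions).
#' @export
meta_region_score <- function(m, features, cell_depth = NULL) {
  idx <- if (is.numeric(features)) as.integer(features)
         else match(features, m$features$feature_id)
  if (anyNA(idx) || any(idx < 1 | idx > ncol(m$counts))) {
    bad <- if (is.numeric(features)) features[is.na(idx) | idx < 1] else
      features[is.na(idx)]
    stopf("region(s) absent from matrix: %s",
          paste(head(bad, 5), collapse = ", "))
  }
  depth <- if (is.null(cell_depth)) Matrix::rowSums(m$counts) else cell_depth
  norm_factor <- ifelse(depth > 0, median(depth[depth > 0]) / depth, 0)
  X <- as.matrix(m$counts[, idx, drop = FALSE]) * norm_factor
  mx <- apply(X, 2, max)
  mx[mx == 0] <- 1
  X <- sweep(X, 2, mx, "/")
  s <- rowSums(X)
  names(s) <- m$cells
  attr(s, "region_matrix") <- X
  s
}

#' Loess fit with 95% confidence band
#'
#' Tricube-weighted local linear regression (degree 1) evaluated on a grid,
#' with pointwise 95% intervals from the local standard error.
#'
#' @param t,y predictor (e.g. pseudotime) and response.
#' @param span loess span.
#' @param grid_n evaluation grid size.
#' @return data.frame with `t`, `fit`, `lower`, `upper`.
#' @export
loess_fit <- function(t, y, span = 0.75, grid_n = 100) {
  ok <- is.finite(t) & is.finite(y)
  fit <- loess(y ~ t, data = data.frame(t = t[ok], y = y[ok]), span = span,
               degree = 1, family = "gaussian",
               control = stats::loess.control(surface = "direct"))
  grid <- seq(min(t[ok]), max(t[ok]), length.out = grid_n)
  pr <- predict(fit, newdata = data.frame(t = grid), se = TRUE)
  data.frame(t = grid, fit = as.numeric(pr$fit),
             lower = as.numeric(pr$fit - 1.96 * pr$se.fit),
             upper = as.numeric(pr$fit + 1.96 * pr$se.fit))
}

# Loess-smoothed half-maximum crossing time of a signal over pseudotime bins.
halfmax_midpoint <- function(t_bins, signal, span = 0.5) {
  sm <- tryCatch(
    predict(loess(signal ~ t_bins, span = span, degree = 1,
                  control = stats::loess.control(surface = "direct"))),
    error = function(e) signal)
  sm <- pmax(sm, 0)
  half <- max(sm) / 2
  idx <- which(sm >= half)
  if (!length(idx)) return(NA_real_)
  t_bins[idx[1]]
}

#' Stratify gaining regions into two temporal waves
#'
#' Rows (regions) of a region-by-cell signal matrix are averaged within
#' pseudotime bins, standardized, and clustered by k-means (k = 2, 50 seeded
#' restarts). Labels are relabeled so wave 1 has the earlier mean half-max
#' midpoint, where each region's midpoint is the first pseudotime bin at
#' which its loess-smoothed profile exceeds half its maximum.
#'
#' @param region_by_cell matrix regions x cells (normalized signal).
#' @param pseudotime per-cell pseudotime in [0, 1].
#' @param k number of clusters (2 for the two-wave model).
#' @param n_bins pseudotime bins.
#' @param seed integer seed for the k-means restarts.
#' @return a `WaveAssignment`: `wave` (factor wave1/wave2 per region),
#'   `midpoint` (per-region half-max pseudotime), `binned` (region x bin
#'   means), `bin_centers`.
#' @export
stratify_waves <- function(region_by_cell, pseudotime, k = 2, n_bins = 25,
                           seed = 1L) {
  X <- as.matrix(region_by_cell)
  if (nrow(unique(X)) < k) stopf("fewer than k = %d distinct regions", k)
  bins <- cut(pseudotime, breaks = seq(0, 1, length.out = n_bins + 1),
              include.lowest = TRUE)
  centers <- (seq_len(n_bins) - 0.5) / n_bins
  B <- t(apply(X, 1, function(row) tapply(row, bins, mean)))
  B[is.na(B)] <- 0
  keep_bins <- which(table(bins) > 0)
  Bz <- t(scale(t(B[, keep_bins, drop = FALSE])))
  Bz[!is.finite(Bz)] <- 0
  if (all(Bz == 0)) {
    warnf("degenerate clustering: all region profiles are flat over pseudotime")
    Bz <- B[, keep_bins, drop = FALSE]  # fall back to unstandardized profiles
  }
  km <- with_seed(seed, kmeans(Bz, centers = k, nstart = 50, iter.max = 100))
  mid <- apply(B[, keep_bins, drop = FALSE], 1, function(sig)
    halfmax_midpoint(centers[keep_bins], sig))
  mean_mid <- tapply(mid, km$cluster, mean, na.rm = TRUE)
  ord <- order(mean_mid)  # earliest mean midpoint -> wave1
  relabel <- match(km$cluster, ord)
  wave <- factor(paste0("wave", relabel), levels = paste0("wave", seq_len(k)))
  names(wave) <- rownames(X)
  structure(list(wave = wave, midpoint = mid, binned = B,
                 bin_centers = centers, kmeans = km),
            class = "WaveAssignment")
}

#' Cross-correlation lag between two binned series
#'
#' Lag at the maximum of the normalized cross-correlation (each overlapping
#' window mean-centered and scale-normalized, i.e. the Pearson correlation
#' of the overlap, as in template-matching NCC — plain global centering is
#' biased toward zero lag for saturating curves); positive lag means `a`
#' leads `b` (b repeats a's values `lag` bins later). Ties are broken toward
#' the smallest |lag|.
#'
#' @param a,b numeric series over the same pseudotime bins.
#' @param max_lag largest |lag| searched (default: half the series length).
#' @return list with `lag` (bins) and `correlation` at the optimum.
#' @export
lag_estimate <- function(a, b, max_lag = floor(length(a) / 2)) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  lags <- -max_lag:max_lag
  cc <- vapply(lags, function(l) {
    if (l >= 0) { ai <- seq_len(n - l); bi <- ai + l }
    else { bi <- seq_len(n + l); ai <- bi - l }
    if (length(ai) < 3) return(-Inf)
    sa <- a[ai] - mean(a[ai]); sb <- b[bi] - mean(b[bi])
    den <- sqrt(sum(sa^2) * sum(sb^2))
    if (den == 0) return(-Inf)
    sum(sa * sb) / den
  }, numeric(1))
  best <- order(-cc, abs(lags))[1]
  list(lag = lags[best], correlation = cc[best])
}
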