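#' Gene activity matrix from fragments
#'
#' Entry (g, c) counts cell c's fragments overlapping gene g's body extended
#' `upstream_bp` upstream of the transcription start, strand-aware. Genes
#' are supplied as a data.frame (chrom, start, end, strand, gene_id; 0-based
#' half-open) or a GRanges.
#'
#' @param fragments fragment data.frame.
#' @param genes gene annotation (data.frame or GRanges with `gene_id`).
#' @param upstream_bp upstream extension from the TSS.
#' @param cells barcodes to include.
#' @param modality label stored on the result.
#' @return a `GeneActivityMatrix`: [modality_matrix()]-like list with
#'   `counts` genes x cells, `genes` table, `cells`, `modality`.
#' @export
gene_activity <- function(fragments, genes, upstream_bp = 2000, cells,
                          modality = fragments$modality[1]) {
  if (is.data.frame(genes)) {
    need <- c("chrom", "start", "end", "gene_id")
    miss <- setdiff(need, names(genes))
    if (length(miss)) stopf("gene annotation record(s) malformed: missing %s",
                            paste(miss, collapse = ", "))
    if (!"strand" %in% names(genes)) genes$strand <- "+"
    bad <- which(genes$start >= genes$end | !genes$strand %in% c("+", "-"))
    if (length(bad)) stopf("malformed gene annotation at record %d", bad[1])
    gr <- df_to_granges(genes[setdiff(names(genes), "strand")])
    GenomicRanges::strand(gr) <- genes$strand
  } else gr <- genes
  ext <- GenomicRanges::resize(gr, GenomicRanges::width(gr) + upstream_bp,
                               fix = "end")
  ext <- GenomicRanges::trim(ext)
  counts <- Matrix::t(count_overlap_matrix(fragments, ext, cells))
  rownames(counts) <- gr$gene_id
  colnames(counts) <- cells
  structure(list(counts = counts, genes = granges_to_df(gr), cells = cells,
                 modality = modality), class = "GeneActivityMatrix")
}

#' k-nearest-neighbor moment smoothing
#'
#' Replaces each cell's profile by the mean over its k nearest embedding
#' neighbors (self included) — the first-moment smoothing required before a
#' steady-state velocity fit. `k = 1` is the identity.
#'
#' @param x genes x cells matrix (or `GeneActivityMatrix`).
#' @param embedding cells x d coordinates (or `Embedding`).
#' @param k neighborhood size including self.
#' @return dense genes x cells smoothed matrix.
#' @export
knn_moments <- function(x, embedding, k = 30) {
  X <- if (is.list(x) && !is.null(x$counts)) x$counts else x
  X <- as.matrix(X)
  coords <- if (inherits(embedding, "Embedding")) embedding$coords else embedding
  n <- ncol(X)
  stopifnot(nrow(coords) == n)
  k <- min(k, n)
  if (k <= 1) return(X)
  dm <- as.matrix(dist(coords))
  W <- matrix(0, n, n)
  for (i in seq_len(n)) W[i, order(dm[i, ])[seq_len(k)]] <- 1 / k
  out <- X %*% t(W)
  dimnames(out) <- dimnames(X)
  out
}

#' Steady-state ratio fit for one gene
#'
#' Least-squares slope of u on s through the origin, fitted on the union of
#' the top and bottom `q` quantiles of s (the presumed steady-state
#' extremes); the slope is clipped at 0 and the squared Pearson correlation
#' on the extreme set is reported as R^2.
#'
#' @param u,s smoothed leading (ATAC) and lagging (H3K27ac) signal for one
#'   gene across cells.
#' @param q extreme-quantile parameter.
#' @return list with `gamma`, `r2`, `fit` (FALSE when s is all zero).
#' @export
fit_gamma <- function(u, s, q = 0.05) {
  stopifnot(length(u) == length(s))
  if (length(s) < 20) stopf("need >= 20 cells for the steady-state fit")
  if (all(s == 0)) return(list(gamma = NA_real_, r2 = NA_real_, fit = FALSE))
  lo <- quantile(s, q); hi <- quantile(s, 1 - q)
  idx <- which(s <= lo | s >= hi)
  if (sum(s[idx]^2) == 0) idx <- seq_along(s)
  gamma <- max(0, sum(u[idx] * s[idx]) / sum(s[idx]^2))
  r2 <- if (sd(u[idx]) == 0 || sd(s[idx]) == 0) 0 else cor(u[idx], s[idx])^2
  list(gamma = gamma, r2 = r2, fit = TRUE)
}

#' Steady-state chromatin velocity model
#'
#' ATAC gene activity is treated as the leading ("unspliced") layer u and
#' H3K27ac as the lagging ("spliced") layer s. Both layers are kNN-smoothed
#' in the embedding, a per-gene steady-state ratio gamma is fitted on the
#' phase extremes, and the residual velocity is v = u - gamma * s. Genes
#' with all-zero s are flagged unfit, and — as is standard for steady-state
#' velocity — only "velocity genes" whose extreme-set fit explains the data
#' (`r2 >= min_r2`, `gamma > 0`) contribute to v; genes without a coherent
#' u-s relationship carry no directional information.
#'
#' @param u_mat,s_mat `GeneActivityMatrix` (or genes x cells matrices) with
#'   identical gene sets.
#' @param embedding cells x d coordinates used for smoothing.
#' @param k smoothing neighborhood.
#' @param q extreme-quantile parameter of the gamma fit.
#' @param min_r2 floor on the squared correlation between the *raw* u and s
#'   layers for a gene to count as a velocity gene (set to 0 together with
#'   `gate_alpha = 1` to keep all fit genes). Selection deliberately uses
#'   the unsmoothed layers: after kNN smoothing any two genes share the
#'   embedding's long-range structure and background-only genes would pass a
#'   smoothed-R^2 gate by chance.
#' @param gate_alpha family-wise error budget for the correlation gate: the
#'   effective threshold is `max(min_r2, qchisq(1 - gate_alpha/G, 1)/n)` for
#'   G genes and n cells (under independence, n * r^2 is asymptotically
#'   chi-square(1)), so a background-only gene slips through with
#'   probability about `gate_alpha` per model fit regardless of scale. A
#'   single leaked gene with monotone s is enough to orient a projected
#'   field, so the gate is deliberately strict.
#' @param normalize size-normalize each layer per cell (scaled to the median
#'   size) before smoothing; without this, shared per-cell depth induces
#'   spurious u-s correlation in every gene.
#' @param u_depth,s_depth per-cell size factors for the two layers — pass
#'   each cell's total fragment count in the respective modality. Defaults
#'   to the layer's column totals, which is only adequate when the gene set
#'   covers most of the signal: totals over a small dynamic gene set rise
#'   with the trajectory and normalizing by them distorts every gene.
#' @param min_counts genes with fewer raw counts than this in either layer
#'   are excluded before fitting (standard velocity preprocessing; genes
#'   with background-only signal otherwise pass the R^2 gate by
#'   smoothing-induced chance correlation).
#' @return a `VelocityModel`: `gamma`, `r2`, `fit` (velocity-gene flag) per
#'   gene; smoothed `u`, `s`; `v` (velocity genes x cells); gene and cell
#'   names.
#' @export
velocity_model <- function(u_mat, s_mat, embedding, k = 30, q = 0.05,
                           min_r2 = 0.01, gate_alpha = 0.001,
                           normalize = TRUE, min_counts = 20,
                           u_depth = NULL, s_depth = NULL) {
  U <- if (is.list(u_mat) && !is.null(u_mat$counts)) as.matrix(u_mat$counts) else as.matrix(u_mat)
  S <- if (is.list(s_mat) && !is.null(s_mat$counts)) as.matrix(s_mat$counts) else as.matrix(s_mat)
  if (!identical(dim(U), dim(S))) stopf("u and s layers must share genes and cells")
  if (!is.null(rownames(U)) && !is.null(rownames(S)) &&
      !identical(rownames(U), rownames(S)))
    stopf("gene sets differ between layers")
  enough <- rowSums(U) >= min_counts & rowSums(S) >= min_counts
  if (normalize) {
    norm_cols <- function(X, size) {
      if (is.null(size)) size <- colSums(X)
      f <- ifelse(size > 0, median(size[size > 0]) / size, 0)
      sweep(X, 2, f, "*")
    }
    U <- norm_cols(U, u_depth)
    S <- norm_cols(S, s_depth)
  }
  Us <- knn_moments(U, embedding, k)
  Ss <- knn_moments(S, embedding, k)
  r2_raw <- vapply(seq_len(nrow(U)), function(g) {
    if (sd(U[g, ]) == 0 || sd(S[g, ]) == 0) 0 else cor(U[g, ], S[g, ])^2
  }, numeric(1))
  fits <- lapply(seq_len(nrow(Us)), function(g) fit_gamma(Us[g, ], Ss[g, ], q))
  gamma <- vapply(fits, `[[`, numeric(1), "gamma")
  r2 <- vapply(fits, `[[`, numeric(1), "r2")
  thr <- min_r2
  if (gate_alpha < 1 && nrow(U) > 0) {
    thr <- max(min_r2, stats::qchisq(1 - gate_alpha / nrow(U), df = 1) / ncol(U))
  }
  fit <- vapply(fits, `[[`, logical(1), "fit") & enough & r2_raw >= thr &
    !is.na(gamma) & gamma > 0
  v <- Us[fit, , drop = FALSE] - gamma[fit] * Ss[fit, , drop = FALSE]
  structure(list(gamma = gamma, r2 = r2, r2_raw = r2_raw, fit = fit,
                 u = Us, s = Ss, v = v,
                 genes = rownames(U), cells = colnames(U), q = q),
            class = "VelocityModel")
}

#' Residual velocity v = u - gamma * s
#'
#' @param u,s smoothed layers (genes x cells).
#' @param gamma per-gene steady-state ratios (NA = unfit, excluded).
#' @return velocity matrix for fit genes.
#' @export
compute_velocity <- function(u, s, gamma) {
  fit <- !is.na(gamma)
  u[fit, , drop = FALSE] - gamma[fit] * s[fit, , drop = FALSE]
}

#' Project velocities onto a 2-D embedding
#'
#' For each cell i and embedding neighbor j, the transition probability is
#' proportional to exp(cos(v_i, s_j - s_i) / sigma) (cosine in gene space,
#' row-normalized over the neighborhood); the field is the
#' probability-weighted mean displacement minus the unweighted neighborhood
#' mean (removing the density drift). Cells with zero velocity get a zero
#' vector.
#'
#' @param model a [velocity_model()] (or a list with `v` and `s` for the fit
#'   genes).
#' @param embedding cells x 2 coordinates.
#' @param k neighborhood size.
#' @param sigma cosine kernel scale.
#' @return a `VelocityField`: `field` (cells x 2), `transition` (sparse
#'   row-stochastic over neighborhoods).
#' @export
project_velocity <- function(model, embedding, k = 30, sigma = 0.05) {
  coords <- if (inherits(embedding, "Embedding")) embedding$coords else embedding
  coords <- as.matrix(coords)[, 1:2, drop = FALSE]
  v <- model$v
  s <- model$s[if (!is.null(model$fit)) model$fit else TRUE, , drop = FALSE]
  n <- ncol(v)
  nn <- knn_indices(coords, min(k, n - 1))
  field <- matrix(0, n, 2)
  ti <- list()
  for (i in seq_len(n)) {
    js <- nn[i, ]
    vi <- v[, i]
    nv <- sqrt(sum(vi^2))
    delta_e <- coords[js, , drop = FALSE] -
      matrix(coords[i, ], length(js), 2, byrow = TRUE)
    if (nv == 0) {
      pij <- rep(1 / length(js), length(js))
      # zero velocity -> zero field by contract
      field[i, ] <- 0
    } else {
      ds <- s[, js, drop = FALSE] - s[, i]
      dn <- sqrt(colSums(ds^2))
      cosv <- ifelse(dn > 0, as.numeric(crossprod(ds, vi)) / (dn * nv), 0)
      w <- exp(cosv / sigma)
      pij <- w / sum(w)
      field[i, ] <- colSums(pij * delta_e) - colMeans(delta_e)
    }
    ti[[i]] <- data.frame(i = i, j = js, p = pij)
  }
  tt <- do.call(rbind, ti)
  transition <- Matrix::sparseMatrix(i = tt$i, j = tt$j, x = tt$p, dims = c(n, n))
  structure(list(field = field, transition = transition, sigma = sigma, k = k),
            class = "VelocityField")
}

#' Rank velocity driver genes
#'
#' Genes ranked by R^2 of the steady-state fit times the variance of their
#' residual velocity across cells; unfit and constant genes are excluded.
#'
#' @param model a [velocity_model()].
#' @param top_n genes returned.
#' @return data.frame gene / score / r2 / v_variance, sorted by score.
#' @export
rank_drivers <- function(model, top_n = 20) {
  fit_idx <- which(model$fit)
  vvar <- apply(model$v, 1, var)
  score <- model$r2[fit_idx] * vvar
  keep <- vvar > 0
  out <- data.frame(gene = model$genes[fit_idx][keep],
                    score = score[keep], r2 = model$r2[fit_idx][keep],
                    v_variance = vvar[keep], stringsAsFactors = FALSE)
  out <- out[order(-out$score), , drop = FALSE]
  rownames(out) <- NULL
  head(out, top_n)
}

# Unit direction of increasing t at each cell, from the binned centroid path
# of the embedding over a known ordering (used to score field alignment).
direction_from_time <- function(coords, t, n_bins = 10) {
  bins <- cut(t, breaks = quantile(t, seq(0, 1, length.out = n_bins + 1)),
              include.lowest = TRUE)
  cent <- apply(coords[, 1:2, drop = FALSE], 2, function(v) tapply(v, bins, mean))
  nb <- nrow(cent)
  dir_bin <- matrix(0, nb, 2)
  for (b in seq_len(nb)) {
    lo <- max(1, b - 1); hi <- min(nb, b + 1)
    dir_bin[b, ] <- cent[hi, ] - cent[lo, ]
  }
  d <- dir_bin[as.integer(bins), , drop = FALSE]
  nrm <- sqrt(rowSums(d^2))
  d / ifelse(nrm > 0, nrm, 1)
}

#' Alignment of a velocity field with a known temporal direction
#'
#' Mean cosine between per-cell field vectors and the local direction of
#' increasing latent time, plus a one-sided randomization p-value. The null
#' rotates every cell's field vector by an independent uniform angle, which
#' makes the null mean cosine exactly zero; permuting vectors across cells
#' instead would retain the coupling between the field's global mean
#' direction and the path's, biasing the null.
#'
#' @param field a [project_velocity()] result (or cells x 2 matrix).
#' @param embedding cells x 2 coordinates.
#' @param t per-cell latent time / pseudotime.
#' @param n_perm randomizations.
#' @param seed integer seed.
#' @return list with `mean_cosine`, `p_value`, `per_cell_cosine`.
#' @export
field_alignment <- function(field, embedding, t, n_perm = 200, seed = 1L) {
  f <- if (inherits(field, "VelocityField")) field$field else field
  coords <- if (inherits(embedding, "Embedding")) embedding$coords else embedding
  d <- direction_from_time(as.matrix(coords), t)
  cos_one <- function(fm) {
    nf <- sqrt(rowSums(fm^2))
    ok <- nf > 0
    if (!any(ok)) return(0)
    mean(rowSums(fm[ok, , drop = FALSE] * d[ok, , drop = FALSE]) / nf[ok])
  }
  obs <- cos_one(f)
  perm <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
    th <- runif(nrow(f), 0, 2 * pi)
    rot <- cbind(cos(th) * f[, 1] - sin(th) * f[, 2],
                 sin(th) * f[, 1] + cos(th) * f[, 2])
    cos_one(rot)
  }, numeric(1)))
  p <- (1 + sum(perm >= obs)) / (n_perm + 1)
  list(mean_cosine = obs, p_value = p,
       per_cell_cosine = rowSums(f * d) / pmax(sqrt(rowSums(f^2)), .Machine$double.eps))
}

#' Anti-correlated-marks velocity negative control
#'
#' Runs the full steady-state velocity pipeline with H3K27ac as the leading
#' layer and H3K27me3 as the lagging layer — a mark pair whose relationship
#' violates the model's precursor-product assumption — and reports the
#' field's alignment with the known trajectory direction. On data with a
#' genuine ATAC-to-H3K27ac lag, the ATAC/H3K27ac field aligns with the
#' trajectory while this control does not.
#'
#' @param u_mat H3K27ac gene activity (leading layer of the control).
#' @param s_mat H3K27me3 gene activity (lagging layer of the control).
#' @param embedding cells x d coordinates (first two used for projection).
#' @param t known latent time / pseudotime for the alignment score.
#' @param k,q,sigma,n_perm,seed passed to the underlying steps.
#' @return list with `model`, `field`, `alignment`.
#' @export
negative_control <- function(u_mat, s_mat, embedding, t, k = 30, q = 0.05,
                             sigma = 0.05, n_perm = 200, seed = 1L,
                             u_depth = NULL, s_depth = NULL) {
  model <- velocity_model(u_mat, s_mat, embedding, k = k, q = q,
                          u_depth = u_depth, s_depth = s_depth)
  field <- project_velocity(model, embedding, k = k, sigma = sigma)
  alignment <- field_alignment(field, embedding, t, n_perm = n_perm, seed = seed)
  list(model = model, field = field, alignment = alignment)
}
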