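test_that("LSI finds planted low-rank structure with orthogonal factors", {
  set.seed(61)
  base <- rbind(matrix(rep(c(8, 0, 4, 0), 25), 1), matrix(rep(c(0, 6, 0, 2), 25), 1))
  X <- base[rep(1:2, each = 40), ] + matrix(rpois(80 * 100, 0.2), 80)
  rownames(X) <- paste0("c", 1:80)
  emb <- lsi(Matrix::Matrix(X, sparse = TRUE), d = 6)
  sv <- emb$all_singular_values
  expect_gt(sv[2] / sv[3], 3)  # two dominant components
  expect_equal(crossprod(emb$u), diag(ncol(emb$u)), tolerance = 1e-8,
               ignore_attr = TRUE)
  # planted types linearly separable in the top components
  lab <- rep(1:2, each = 40)
  cent <- rbind(colMeans(emb$coords[lab == 1, 1:2]),
                colMeans(emb$coords[lab == 2, 1:2]))
  assign_nearest <- apply(emb$coords[, 1:2], 1, function(p)
    which.min(colSums((t(cent) - p)^2)))
  expect_true(mean(assign_nearest == lab) %in% c(0, 1) ||
                mean(assign_nearest == lab) > 0.95)
})

test_that("requesting too many components warns and truncates", {
  X <- Matrix::Matrix(matrix(rpois(40, 1), 4, 10), sparse = TRUE)
  rownames(X) <- paste0("c", 1:4)
  expect_warning(emb <- lsi(X, d = 10), "rank")
  expect_lte(ncol(emb$coords), 3)
})

test_that("SNN clustering separates planted blobs deterministically", {
  set.seed(62)
  pts <- rbind(matrix(rnorm(200, 0), ncol = 2),
               matrix(rnorm(200, 8), ncol = 2))
  # modest resolution: at these small per-blob sizes modularity at
  # resolution 1 subdivides a homogeneous blob
  lab <- snn_cluster(pts, k_neighbors = 15, resolution = 0.3, seed = 7)
  expect_identical(length(unique(lab)), 2L)
  truth <- rep(1:2, each = 100)
  expect_equal(mclust::adjustedRandIndex(lab, truth), 1)
  expect_identical(lab, snn_cluster(pts, k_neighbors = 15, resolution = 0.3,
                                    seed = 7))
  # one blob at low resolution stays one cluster
  one <- matrix(rnorm(300), ncol = 2)
  expect_identical(length(unique(snn_cluster(one, resolution = 0.1, seed = 7))), 1L)
})

test_that("rank-sum test matches enumeration and the reference implementation", {
  # frozen hand case: U = 0, exact two-sided p = 2/20
  res <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$p, 0.1)
  expect_true(res$exact)
  # identical multisets -> p = 1 (tie-corrected approximation path)
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "non-empty")
  # exact path equals full enumeration for all group sizes <= 8 (no ties)
  set.seed(63)
  for (i in 1:25) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    v <- sample(1000, n1 + n2)           # distinct -> no ties
    x <- v[seq_len(n1)]; y <- v[-seq_len(n1)]
    got <- wilcoxon_rank_sum(x, y)
    expect_true(got$exact)
    expect_equal(got$p, wilcoxon_enum_oracle(x, y))
    ref <- wilcox.test(x, y, exact = TRUE)
    expect_equal(got$p, ref$p.value)
    expect_equal(got$U, unname(ref$statistic))
  }
  # normal-approximation path stays within 0.01 of full enumeration (9 vs 9,
  # just past the exact-policy cutoff)
  set.seed(64)
  for (i in 1:5) {
    v <- sample(1000, 18)
    x <- v[1:9]; y <- v[10:18]
    got <- wilcoxon_rank_sum(x, y)
    expect_false(got$exact)
    expect_lt(abs(got$p - wilcoxon_enum_oracle(x, y)), 0.01)
  }
  # tied data agree with the reference continuity-corrected approximation
  set.seed(65)
  for (i in 1:10) {
    x <- sample(1:5, 15, replace = TRUE)
    y <- sample(2:6, 18, replace = TRUE)
    got <- wilcoxon_rank_sum(x, y)
    ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
    expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("marker ranking recovers planted markers with correct capture rates", {
  ds <- small_dataset()
  st <- cells_of(ds, "static")
  m <- cached("small_static_bm_atac",
              build_bin_matrix(ds$fragments$ATAC, ds$truth$config$genome, 5000, st))
  lab <- type_of(ds, st)
  mk <- rank_markers(m, lab, top_n = 200)
  expect_true(all(mk$p >= 0 & mk$p <= 1))
  expect_true(all(mk$capture_rate >= 0 & mk$capture_rate <= 1))
  # capture rate equals the direct nonzero fraction
  one <- mk[1, ]
  idx <- lab == one$cluster
  expect_equal(one$capture_rate,
               mean(as.matrix(m$counts)[idx, one$feature_index] > 0))
  # planted ATAC markers appear in their own type's list
  reg <- ds$truth$regions
  pl <- reg[reg$role == "static-marker" & reg$modality == "ATAC", ]
  hit <- vapply(seq_len(nrow(pl)), function(i) {
    sub <- mk[mk$cluster == pl$type[i], ]
    fb <- m$features[sub$feature_index, ]
    any(fb$chrom == pl$chrom[i] & fb$start < pl$end[i] & fb$end > pl$start[i])
  }, logical(1))
  expect_gte(mean(hit), 0.9)
  # a label with no enriched features yields an empty list
  set.seed(66)
  flat <- modality_matrix(Matrix::Matrix(matrix(rpois(50 * 30, 1), 50), sparse = TRUE),
                          data.frame(chrom = "chrA", start = 0:29 * 10,
                                     end = 0:29 * 10 + 10, kind = "bin",
                                     feature_id = paste0("f", 1:30)),
                          paste0("c", 1:50))
  mk_flat <- rank_markers(flat, rep(c("a", "b"), 25), p_max = 1e-4)
  expect_identical(nrow(mk_flat), 0L)
  expect_warning(rank_markers(flat, c("tiny", rep("big", 49))), "skipped")
})

test_that("pseudobulk PCA groups split halves of the same population", {
  ds <- small_dataset()
  st <- cells_of(ds, "static")
  lab <- type_of(ds, st)
  # split each type into two pseudo-replicates
  set.seed(67)
  half <- ave(seq_along(lab), lab, FUN = function(i)
    sample(rep(1:2, length.out = length(i))))
  lab2 <- paste0(lab, "_h", half)
  mats <- list(
    ATAC = cached("small_static_bm_atac",
                  build_bin_matrix(ds$fragments$ATAC, ds$truth$config$genome, 5000, st)),
    H3K27ac = cached("small_static_bm_k27ac",
                     build_bin_matrix(ds$fragments$H3K27ac, ds$truth$config$genome,
                                      5000, st)))
  pb <- pseudobulk_pca(mats, lab2, top_k = 20)
  expect_equal(crossprod(pb$rotation[, 1:3]), diag(3), tolerance = 1e-8,
               ignore_attr = TRUE)
  # halves of the same type are mutually nearest within their modality
  sc <- pb$scores[, 1:3, drop = FALSE]
  keys <- pb$profiles
  for (mod in names(mats)) {
    for (ty in unique(lab)) {
      i <- which(keys$modality == mod & keys$cluster == paste0(ty, "_h1"))
      j <- which(keys$modality == mod & keys$cluster == paste0(ty, "_h2"))
      others <- which(keys$modality == mod & !grepl(paste0("^", ty, "_"), keys$cluster))
      d_self <- sum((sc[i, ] - sc[j, ])^2)
      d_other <- min(colSums((t(sc[others, , drop = FALSE]) - sc[i, ])^2))
      expect_lt(d_self, d_other)
    }
  }
  # duplicated input matrices give coincident pseudobulk PCA points
  m1 <- mats$ATAC
  pb2 <- pseudobulk_pca(list(a = m1, b = m1), lab, top_k = 10)
  k2 <- pb2$profiles
  for (ty in unique(lab)) {
    i <- which(k2$modality == "a" & k2$cluster == ty)
    j <- which(k2$modality == "b" & k2$cluster == ty)
    expect_lt(sum((pb2$scores[i, ] - pb2$scores[j, ])^2), 1e-12)
  }
})
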