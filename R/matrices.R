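#' Sparse cells-by-features modality matrix
#'
#' Lightweight container holding a sparse non-negative count matrix (rows =
#' cells, columns = features), a feature table (interval or gene id plus
#' kind) and the modality label.
#'
#' @param counts `dgCMatrix` cells x features.
#' @param features data.frame describing columns (chrom/start/end or gene_id,
#'   plus `kind`).
#' @param cells character vector of row barcodes.
#' @param modality modality label.
#' @return a `ModalityMatrix`.
#' @export
modality_matrix <- function(counts, features, cells, modality = NA_character_) {
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "CsparseMatrix"), "generalMatrix")
  if (nrow(counts) != length(cells)) stopf("cells do not match matrix rows")
  if (ncol(counts) != nrow(features)) stopf("features do not match matrix columns")
  if (any(counts@x < 0)) stopf("counts must be non-negative")
  rownames(counts) <- cells
  structure(list(counts = counts, features = features, cells = cells,
                 modality = modality), class = "ModalityMatrix")
}

#' @export
dim.ModalityMatrix <- function(x) dim(x$counts)

#' @method print ModalityMatrix
#' @export
print.ModalityMatrix <- function(x, ...) {
  cat(sprintf("ModalityMatrix [%s]: %d cells x %d features (%s), %.2f%% nonzero\n",
              x$modality, nrow(x$counts), ncol(x$counts),
              paste(unique(x$features$kind), collapse = ","),
              100 * length(x$counts@x) / max(1, prod(dim(x$counts)))))
  invisible(x)
}

count_overlap_matrix <- function(fragments, target_gr, cells, genome = NULL) {
  keep <- fragments$cell %in% cells
  fragments <- fragments[keep, , drop = FALSE]
  ci <- match(fragments$cell, cells)
  if (nrow(fragments)) {
    fr <- df_to_granges(fragments)
    ov <- GenomicRanges::findOverlaps(fr, target_gr)
    counts <- Matrix::sparseMatrix(
      i = ci[S4Vectors::queryHits(ov)], j = S4Vectors::subjectHits(ov),
      x = rep(1, length(ov)), dims = c(length(cells), length(target_gr)))
  } else {
    counts <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                   dims = c(length(cells), length(target_gr)))
  }
  counts
}

#' Build a genome-bin count matrix
#'
#' Entry (c, b) counts cell c's fragments overlapping bin b; a fragment
#' spanning k bins increments k entries (overlap counting, matching
#' feature-matrix construction for tagmentation data). Bins tile the genome
#' without overlap at `bin_bp` (5 kb by default).
#'
#' @param fragments fragment data.frame.
#' @param genome named chromosome lengths.
#' @param bin_bp bin width.
#' @param cells barcodes to include (rows retained even if all zero).
#' @param modality label stored on the result.
#' @return a [modality_matrix()] with bin features.
#' @export
build_bin_matrix <- function(fragments, genome, bin_bp = 5000, cells,
                             modality = fragments$modality[1]) {
  fragments <- validate_fragments(fragments, genome)
  bins <- genome_bins(genome, bin_bp)
  feats <- granges_to_df(bins)
  feats$kind <- "bin"
  feats$feature_id <- sprintf("%s:%d-%d", feats$chrom, feats$start, feats$end)
  modality_matrix(count_overlap_matrix(fragments, bins, cells), feats, cells, modality)
}

#' Build a peak count matrix
#'
#' Entry (c, p) counts cell c's fragments overlapping (>= 1 bp) peak p.
#'
#' @param peaks `GRanges` peak set.
#' @inheritParams build_bin_matrix
#' @return a [modality_matrix()] with peak features.
#' @export
build_peak_matrix <- function(fragments, peaks, cells,
                              modality = fragments$modality[1]) {
  fragments <- validate_fragments(fragments)
  feats <- if (length(peaks)) granges_to_df(peaks)[c("chrom", "start", "end")]
           else data.frame(chrom = character(), start = integer(), end = integer())
  feats$kind <- rep("peak", nrow(feats))
  feats$feature_id <- sprintf("%s:%d-%d", feats$chrom, feats$start, feats$end)
  modality_matrix(count_overlap_matrix(fragments, peaks, cells), feats, cells, modality)
}

#' TF-IDF weighting of a count matrix
#'
#' The log term-frequency dialect:
#' `x' = log(1 + 1e4 * (x / rowsum) * (n_cells / df))`, with `df` the number
#' of cells in which the feature is nonzero. Zero rows and zero-df columns
#' stay zero; the sparsity pattern is preserved exactly.
#'
#' @param m a [modality_matrix()] or sparse matrix (cells x features).
#' @return same type as the input, weighted; carries `attr(,"tfidf") = TRUE`.
#' @export
tfidf <- function(m) {
  x <- if (inherits(m, "ModalityMatrix")) m$counts else m
  x <- methods::as(methods::as(x, "CsparseMatrix"), "generalMatrix")
  rs <- Matrix::rowSums(x)
  df <- Matrix::colSums(x > 0)
  trip <- Matrix::summary(x)
  tf <- trip$x / rs[trip$i]
  idf <- nrow(x) / df[trip$j]
  newx <- log1p(1e4 * tf * idf)
  out <- Matrix::sparseMatrix(i = trip$i, j = trip$j, x = newx, dims = dim(x),
                              dimnames = dimnames(x))
  attr(out, "tfidf") <- TRUE
  if (inherits(m, "ModalityMatrix")) {
    m$counts <- out
    attr(m, "tfidf") <- TRUE
    m
  } else out
}

#' Write / read a ModalityMatrix as MatrixMarket + sidecar tables
#'
#' Writes `matrix.mtx`, `barcodes.tsv` and `features.tsv` under `dir`;
#' round-trips losslessly including feature metadata.
#'
#' @param m a [modality_matrix()].
#' @param dir output directory.
#' @return `dir` (write) or the reconstructed `ModalityMatrix` (read).
#' @export
write_matrix <- function(m, dir) {
  stopifnot(inherits(m, "ModalityMatrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(m$counts, file.path(dir, "matrix.mtx"))
  writeLines(m$cells, file.path(dir, "barcodes.tsv"))
  feats <- m$features
  feats$.modality <- rep(m$modality, nrow(feats))
  write.table(feats, file.path(dir, "features.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix")
  cells <- readLines(file.path(dir, "barcodes.tsv"))
  feats <- read.table(file.path(dir, "features.tsv"), sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
  modality <- if (nrow(feats)) feats$.modality[1] else NA_character_
  feats$.modality <- NULL
  modality_matrix(counts, feats, cells, modality)
}
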